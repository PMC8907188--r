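#' Q(lambda) learning parameters
#'
#' Parameters of the tabular Watkins' Q(lambda) agent. Defaults are the study
#' values: learning rate `alpha = 0.2`, discount `gamma = 1` (all interventions
#' count equally regardless of when they occur), eligibility-trace decay
#' `lam = 0.2`, and `epsilon` the probability that each action is chosen
#' uniformly at random rather than greedily.
#'
#' @param alpha Learning rate in (0, 1].
#' @param gamma Discount factor in [0, 1].
#' @param lam Eligibility-trace decay in [0, 1].
#' @param epsilon Per-action random-choice probability in [0, 1].
#' @return An object of class `rl_params`.
#' @export
rl_params <- function(alpha = 0.2, gamma = 1.0, lam = 0.2, epsilon = 1.0) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (!(gamma >= 0 && gamma <= 1)) stop("gamma must be in [0, 1]", call. = FALSE)
  if (!(lam >= 0 && lam <= 1)) stop("lam must be in [0, 1]", call. = FALSE)
  if (!(epsilon >= 0 && epsilon <= 1)) stop("epsilon must be in [0, 1]",
                                            call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma, lam = lam, epsilon = epsilon),
            class = "rl_params")
}

#' Q-value table
#'
#' One Q value per (state, action) pair: a 3 x 3 numeric matrix with states as
#' rows and actions as columns.
#'
#' @param fill Initial value for every entry (default 0).
#' @return A named 3 x 3 matrix.
#' @export
q_table <- function(fill = 0) {
  matrix(fill, nrow = 3L, ncol = 3L,
         dimnames = list(bystander_states(), agent_actions()))
}

#' Eligibility-trace table
#'
#' Accumulating traces: one nonnegative decaying weight per (state, action)
#' pair, same layout as [q_table()].
#'
#' @inheritParams q_table
#' @return A named 3 x 3 matrix.
#' @export
eligibility_traces <- function(fill = 0) {
  q_table(fill)
}

assert_sa_table <- function(x, what = "table") {
  if (!is.matrix(x) || !identical(dim(x), c(3L, 3L)) || any(!is.finite(x)))
    stop(what, " must be a finite 3x3 state-action matrix", call. = FALSE)
  invisible(x)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon`, a uniformly random action is returned and
#' flagged as random (this flag feeds the `proprandom` experimental variable).
#' Otherwise an action maximising `q[s, ]` is returned, breaking ties uniformly
#' at random; tie-break randomness does not set the random flag.
#'
#' @param q A [q_table()].
#' @param s State name, one of [bystander_states()].
#' @param params An [rl_params()].
#' @return List with `action` (name), `random_flag` (logical), and `greedy`
#'   (logical: whether the chosen action attains `max(q[s, ])`, which governs
#'   the Watkins trace cut regardless of how the action was sampled).
#' @export
select_action <- function(q, s, params) {
  assert_sa_table(q, "q")
  stopifnot(s %in% bystander_states())
  actions <- agent_actions()
  row <- q[s, ]
  if (stats::runif(1) < params$epsilon) {
    a <- actions[sample.int(3L, 1L)]
    random_flag <- TRUE
  } else {
    best <- which(row == max(row))
    a <- actions[best[sample.int(length(best), 1L)]]
    random_flag <- FALSE
  }
  list(action = a, random_flag = random_flag, greedy = row[a] == max(row))
}

#' Watkins' Q(lambda) update for one transition
#'
#' Computes the temporal-difference error `delta = r + gamma * max(q[s_next, ])
#' - q[s, a]` (terminal transitions drop the bootstrap term), increments the
#' accumulating trace of the visited pair by 1, and applies `alpha * delta *
#' e` to the whole table.
#'
#' @param q A [q_table()].
#' @param e An [eligibility_traces()] table.
#' @param s,a Visited state and action names.
#' @param r Reward observed for the window.
#' @param s_next Next state name, or `NULL` for a terminal transition.
#' @param params An [rl_params()].
#' @return List with updated `q` and `e`.
#' @export
q_lambda_update <- function(q, e, s, a, r, s_next, params) {
  assert_sa_table(q, "q"); assert_sa_table(e, "e")
  stopifnot(s %in% bystander_states(), a %in% agent_actions())
  bootstrap <- if (is.null(s_next)) 0 else params$gamma * max(q[s_next, ])
  delta <- r + bootstrap - q[s, a]
  e[s, a] <- e[s, a] + 1
  q <- q + params$alpha * delta * e
  list(q = q, e = e)
}

#' Trace decay or Watkins cut after the next action choice
#'
#' In Watkins' Q(lambda) the traces only survive while the agent keeps acting
#' greedily: if the action just chosen is greedy with respect to the current Q
#' table, every trace is decayed by `gamma * lam`; otherwise all traces are
#' zeroed, because credit can no longer be propagated through an off-policy
#' choice.
#'
#' @param e An [eligibility_traces()] table.
#' @param next_greedy Logical: was the next chosen action greedy?
#' @param params An [rl_params()].
#' @return Updated trace table.
#' @export
post_choice_trace_step <- function(e, next_greedy, params) {
  assert_sa_table(e, "e")
  if (isTRUE(next_greedy)) e * (params$gamma * params$lam) else q_table(0)
}

#' Average Q tables across a cohort
#'
#' Element-wise arithmetic mean; used to carry a cohort's learned policy into
#' the next experimental group as its shared initial Q table.
#'
#' @param tables Nonempty list of [q_table()] matrices.
#' @return A single averaged [q_table()].
#' @export
average_q <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("average_q: need a nonempty list of Q tables", call. = FALSE)
  for (t in tables) assert_sa_table(t, "q")
  Reduce(`+`, tables) / length(tables)
}

#' Write a Q table to JSON
#'
#' Serialises the 3 x 3 table with explicit state and action axes plus a
#' metadata block (group label, epsilon, seed), so logged policies are
#' self-describing.
#'
#' @param q A [q_table()].
#' @param path Output file path.
#' @param meta Named list of metadata (e.g. `group`, `epsilon`, `seed`).
#' @return `path`, invisibly.
#' @export
write_q_table <- function(q, path, meta = list()) {
  assert_sa_table(q, "q")
  obj <- list(states = bystander_states(), actions = agent_actions(),
              q = unname(apply(q, 1L, function(r) as.list(unname(r)),
                               simplify = FALSE)),
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Q table written by [write_q_table()]
#'
#' @param path JSON file path.
#' @return List with `q` (the matrix) and `meta`.
#' @export
read_q_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  q <- matrix(unlist(obj$q), nrow = 3L, byrow = TRUE,
              dimnames = list(unlist(obj$states), unlist(obj$actions)))
  obj$meta <- lapply(obj$meta, unlist)
  assert_sa_table(q, "q")
  list(q = q, meta = obj$meta)
}
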