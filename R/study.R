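#' Experimental group specification
#'
#' One of the study's three sequential cohorts. `epsilon` and the label map as
#' in the design: None (`epsilon = 1`, pure random action choice), Medium
#' (`epsilon = 0.66`) and High (`epsilon = 0.33`). All participants in a group
#' share the same initial Q table and epsilon.
#'
#' @param label One of `"None"`, `"Medium"`, `"High"`.
#' @param epsilon Random-choice probability; defaults to the label's design
#'   value.
#' @param n_participants Cohort size (default 15).
#' @param q_init Shared initial [q_table()].
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label = c("None", "Medium", "High"), epsilon = NULL,
                       n_participants = 15L, q_init = q_table(0)) {
  label <- match.arg(label)
  design <- c(None = 1, Medium = 0.66, High = 0.33)
  if (is.null(epsilon)) epsilon <- design[[label]]
  if (!(epsilon >= 0 && epsilon <= 1))
    stop("group_spec: epsilon must be in [0, 1]", call. = FALSE)
  stopifnot(n_participants >= 1L)
  assert_sa_table(q_init, "q_init")
  structure(list(label = label, epsilon = epsilon,
                 n_participants = as.integer(n_participants), q_init = q_init),
            class = "group_spec")
}

#' Run one participant session
#'
#' Plays the full confrontation for one synthetic participant: at each action
#' slot the agent observes the proxemic state, chooses an action
#' (epsilon-greedy), the participant's response over the 10 s window is
#' sampled, the distance band advances one step, the reward is computed and
#' the Watkins' Q(lambda) update applied. A window spent in the
#' `Intervention` band (closer than 0.5 m) automatically counts as a physical
#' intervention. The final slot is terminal: no bootstrap term and no further
#' trace step.
#'
#' @param model A [participant_model()].
#' @param spec A [group_spec()] (supplies epsilon and the initial Q table).
#' @param config A [scenario_config()].
#' @param params An [rl_params()]; its `epsilon` is overridden by the group's.
#' @param seed Optional integer seed for the session's RNG stream.
#' @param start_state State at the first action slot (default `"Passive"`:
#'   the participant starts away from the confrontation).
#' @return An object of class `session_result`: list with `records` (data
#'   frame of one row per slot), `q_final`, `resp`, `proprandom`, `seed`.
#' @export
run_session <- function(model, spec, config = scenario_config(),
                        params = rl_params(), seed = NULL,
                        start_state = "Passive") {
  stopifnot(inherits(model, "participant_model"), inherits(spec, "group_spec"))
  validate_scenario_config(config)
  stopifnot(start_state %in% bystander_states())
  if (!is.null(seed)) set.seed(seed)
  params$epsilon <- spec$epsilon

  q <- spec$q_init
  e <- eligibility_traces(0)
  cur <- utterance_cursor()
  times <- action_schedule(config)
  n <- config$n_slots
  s <- start_state

  rec <- data.frame(
    slot = seq_len(n), time_s = times,
    state = character(n), action = character(n),
    random_flag = logical(n), utterance_index = NA_integer_,
    verbal = logical(n), physical = logical(n),
    reward = numeric(n), y = integer(n))

  pending <- NULL  # transition awaiting its update once s_next is known
  for (k in seq_len(n)) {
    sel <- select_action(q, s, params)
    if (!is.null(pending)) {
      # Watkins trace step keyed to the action just chosen, then the
      # delayed update for the previous transition (s_next = current s).
      e <- post_choice_trace_step(e, sel$greedy, params)
    }
    ui <- NA_integer_
    if (sel$action == "BystandersUtter") {
      nu <- next_utterance(cur); cur <- nu$cursor; ui <- nu$index
    }
    fl <- sample_response(model, sel$action)
    s_next <- step_distance_state(model, s, responded = fl$y == 1L)
    if (s == "Intervention") fl$physical <- TRUE  # automatic physical rule
    y <- as.integer(fl$verbal || fl$physical)
    r <- compute_reward(fl)
    upd <- q_lambda_update(q, e, s, sel$action, r,
                           if (k == n) NULL else s_next, params)
    q <- upd$q; e <- upd$e
    rec$state[k] <- s; rec$action[k] <- sel$action
    rec$random_flag[k] <- sel$random_flag
    rec$utterance_index[k] <- ui
    rec$verbal[k] <- fl$verbal; rec$physical[k] <- fl$physical
    rec$reward[k] <- r; rec$y[k] <- y
    pending <- TRUE
    s <- s_next
  }
  structure(list(records = rec, q_final = q,
                 resp = sum(rec$y),
                 proprandom = mean(rec$random_flag),
                 seed = seed),
            class = "session_result")
}

#' Run one experimental group
#'
#' Runs one session per participant model, all starting from the group's
#' shared initial Q table, and averages the final Q tables.
#'
#' @param models List of [participant_model()]s (one per participant).
#' @param spec A [group_spec()].
#' @param config A [scenario_config()].
#' @param params An [rl_params()].
#' @param seeds Optional integer vector of per-session seeds (same length as
#'   `models`).
#' @return List with `sessions` (list of `session_result`) and `q_mean`.
#' @export
run_group <- function(models, spec, config = scenario_config(),
                      params = rl_params(), seeds = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (!is.null(seeds)) stopifnot(length(seeds) == length(models))
  sessions <- lapply(seq_along(models), function(i) {
    run_session(models[[i]], spec, config, params,
                seed = if (is.null(seeds)) NULL else seeds[[i]])
  })
  q_mean <- average_q(lapply(sessions, `[[`, "q_final"))
  list(sessions = sessions, q_mean = q_mean)
}

derive_session_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full three-cohort study
#'
#' Emulates the accumulating design: the None cohort (`epsilon = 1`) starts
#' from an all-zero Q table; the averaged final Q tables of each cohort seed
#' the next (Medium, `epsilon = 0.66`; then High, `epsilon = 0.33`). Per-session
#' seeds are derived deterministically from `master_seed`, so an identical
#' master seed reproduces the study bit-for-bit.
#'
#' @param n_per_group Participants per cohort (default 15).
#' @param config A [scenario_config()].
#' @param params An [rl_params()].
#' @param sigma_u SD of the per-subject effects of the synthetic population.
#' @param weights Length-3 simplex action weights of the synthetic population.
#' @param master_seed Integer master seed.
#' @param ... Further arguments passed to [participant_model()].
#' @return An object of class `study_result`: list with `participants` (one
#'   row per participant: `id`, `group`, `resp`, `proprandom`, `M`, `H`),
#'   `trials` (one row per trial: `id`, `group`, `slot`, `action`, `vl`, `pl`,
#'   `bu`, `y`), `groups` (per-group session lists and Q means), `q_tables`
#'   (initial/final mean Q per group) and `master_seed`.
#' @export
run_study <- function(n_per_group = 15L, config = scenario_config(),
                      params = rl_params(), sigma_u = 1,
                      weights = c(0.59, 0.29, 0.12),
                      master_seed = 1L, ...) {
  labels <- c("None", "Medium", "High")
  n_total <- 3L * n_per_group
  seeds <- derive_session_seeds(master_seed, n_total + 1L)
  set.seed(seeds[n_total + 1L])
  u <- stats::rnorm(n_total, 0, sigma_u)
  models <- lapply(u, function(ui)
    participant_model(u = ui, weights = weights, ...))

  q_init <- q_table(0)
  groups <- list()
  part_rows <- list()
  trial_rows <- list()
  id0 <- 0L
  for (g in seq_along(labels)) {
    spec <- group_spec(labels[g], n_participants = n_per_group, q_init = q_init)
    idx <- (g - 1L) * n_per_group + seq_len(n_per_group)
    res <- run_group(models[idx], spec, config, params, seeds = seeds[idx])
    groups[[labels[g]]] <- c(res, list(q_init = q_init))
    for (j in seq_len(n_per_group)) {
      sr <- res$sessions[[j]]
      id <- id0 + j
      part_rows[[id]] <- data.frame(
        id = id, group = labels[g], resp = sr$resp,
        proprandom = sr$proprandom,
        M = as.integer(labels[g] == "Medium"),
        H = as.integer(labels[g] == "High"))
      tr <- sr$records
      trial_rows[[id]] <- data.frame(
        id = id, group = labels[g], slot = tr$slot, action = tr$action,
        vl = as.integer(tr$action == "VictimLookAt"),
        pl = as.integer(tr$action == "PerpLookAt"),
        bu = as.integer(tr$action == "BystandersUtter"),
        y = tr$y)
    }
    q_init <- res$q_mean
    id0 <- id0 + n_per_group
  }
  structure(list(participants = do.call(rbind, part_rows),
                 trials = do.call(rbind, trial_rows),
                 groups = groups, master_seed = master_seed),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  m <- tapply(x$participants$resp, x$participants$group, mean)
  cat("Three-cohort study,", nrow(x$participants), "participants,",
      nrow(x$trials), "trials (master seed", x$master_seed, ")\n")
  cat("Mean interventions: None", round(m[["None"]], 2),
      "| Medium", round(m[["Medium"]], 2),
      "| High", round(m[["High"]], 2), "\n")
  invisible(x)
}

event_log_cols <- c("participant_id", "group", "slot", "time_s", "state",
                    "action", "random_flag", "utterance_index", "verbal",
                    "physical", "reward", "y")

#' Write session records to an event-log CSV
#'
#' Schema: `participant_id,group,slot,time_s,state,action,random_flag,
#' utterance_index,verbal,physical,reward,y`; booleans as 0/1, missing
#' utterance index as an empty field, UTF-8.
#'
#' @param sessions A single `session_result` or a list of them.
#' @param path Output CSV path.
#' @param participant_ids Integer ids, one per session (default `1:n`).
#' @param group Group label recorded in each row (recycled).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sessions, path, participant_ids = NULL,
                            group = "None") {
  if (inherits(sessions, "session_result")) sessions <- list(sessions)
  if (is.null(participant_ids)) participant_ids <- seq_along(sessions)
  group <- rep_len(group, length(sessions))
  rows <- lapply(seq_along(sessions), function(i) {
    r <- sessions[[i]]$records
    data.frame(participant_id = participant_ids[i], group = group[i],
               slot = r$slot, time_s = r$time_s, state = r$state,
               action = r$action, random_flag = as.integer(r$random_flag),
               utterance_index = r$utterance_index,
               verbal = as.integer(r$verbal), physical = as.integer(r$physical),
               reward = r$reward, y = r$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an event-log CSV
#'
#' Validates the schema and field types; a malformed row raises an error
#' naming its line number.
#'
#' @param path CSV path written by [write_event_log()].
#' @return Data frame in the event-log schema (booleans as logical).
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  if (!identical(names(df), event_log_cols))
    stop("event log: unexpected columns: ", paste(names(df), collapse = ","),
         call. = FALSE)
  if (nrow(df) == 0L) {
    out <- df
    for (cc in c("participant_id", "slot", "utterance_index", "y"))
      out[[cc]] <- integer(0)
    for (cc in c("time_s", "reward")) out[[cc]] <- numeric(0)
    for (cc in c("random_flag", "verbal", "physical")) out[[cc]] <- logical(0)
    return(out)
  }
  parse_int <- function(col, allow_empty = FALSE) {
    x <- df[[col]]
    bad <- which(!(grepl("^-?[0-9]+$", x) | (allow_empty & x == "")))
    if (length(bad))
      stop(sprintf("event log: bad %s at line %d", col, bad[1L] + 1L),
           call. = FALSE)
    suppressWarnings(as.integer(x))
  }
  parse_bool <- function(col) {
    x <- df[[col]]
    bad <- which(!x %in% c("0", "1"))
    if (length(bad))
      stop(sprintf("event log: non-boolean %s at line %d", col, bad[1L] + 1L),
           call. = FALSE)
    x == "1"
  }
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop(sprintf("event log: bad %s at line %d", col, bad[1L] + 1L),
           call. = FALSE)
    x
  }
  bad_state <- which(!df$state %in% bystander_states())
  if (length(bad_state))
    stop(sprintf("event log: unknown state at line %d", bad_state[1L] + 1L),
         call. = FALSE)
  bad_action <- which(!df$action %in% agent_actions())
  if (length(bad_action))
    stop(sprintf("event log: unknown action at line %d", bad_action[1L] + 1L),
         call. = FALSE)
  data.frame(participant_id = parse_int("participant_id"), group = df$group,
             slot = parse_int("slot"), time_s = parse_num("time_s"),
             state = df$state, action = df$action,
             random_flag = parse_bool("random_flag"),
             utterance_index = parse_int("utterance_index", allow_empty = TRUE),
             verbal = parse_bool("verbal"), physical = parse_bool("physical"),
             reward = parse_num("reward"), y = parse_int("y"))
}
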