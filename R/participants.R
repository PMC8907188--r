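#' Synthetic participant model
#'
#' A generative stand-in for a human bystander. The probability of any
#' intervention in an action window follows the Bernoulli logistic model used
#' for the per-trial analysis: `P(respond) = inv_logit(u + b_vl*[VL] +
#' b_pl*[PL] + b_bu*[BU])`, where `u` is a per-subject effect and the action
#' weights lie on the unit simplex. Given a response, verbal and physical
#' flags are drawn independently (re-drawn until at least one is true).
#' Movement between the three proxemic bands follows a sticky Markov chain
#' with an approach bonus after a response; movement is deliberately simple
#' plumbing, not a cognitive model.
#'
#' @param u Per-subject effect on the logit scale.
#' @param weights Numeric length-3 action weights `(b_vl, b_pl, b_bu)` on the
#'   unit simplex; defaults `(0.59, 0.29, 0.12)`, the posterior means reported
#'   for the three actions, so recovering their ordering is the natural smoke
#'   test.
#' @param p_verbal_given_response,p_physical_given_response Probabilities of
#'   each intervention type given that the participant responds at all.
#' @param move 3 x 3 row-stochastic transition matrix over the states
#'   (nearest-first order); default 0.8 stay / 0.2 to the neighbouring bands.
#' @param approach_bonus Probability mass shifted one band nearer after a
#'   response, applied to the transition row before sampling.
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(u = 0,
                              weights = c(0.59, 0.29, 0.12),
                              p_verbal_given_response = 0.8,
                              p_physical_given_response = 0.4,
                              move = default_move_matrix(),
                              approach_bonus = 0.3) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("participant_model: weights must sum to 1", call. = FALSE)
  stopifnot(p_verbal_given_response >= 0, p_verbal_given_response <= 1,
            p_physical_given_response >= 0, p_physical_given_response <= 1,
            approach_bonus >= 0, approach_bonus <= 1)
  if (!is.matrix(move) || !identical(dim(move), c(3L, 3L)) ||
      any(move < 0) || any(abs(rowSums(move) - 1) > 1e-9))
    stop("participant_model: move must be a 3x3 row-stochastic matrix",
         call. = FALSE)
  dimnames(move) <- list(bystander_states(), bystander_states())
  weights <- stats::setNames(weights, agent_actions())
  structure(list(u = u, weights = weights,
                 p_verbal_given_response = p_verbal_given_response,
                 p_physical_given_response = p_physical_given_response,
                 move = move, approach_bonus = approach_bonus),
            class = "participant_model")
}

#' Default movement transition matrix
#'
#' Mildly sticky: 0.8 probability of staying in the current band, 0.2 split
#' between the neighbouring bands (all 0.2 to the single neighbour for the
#' edge bands), chosen so that all three states occur in typical sessions.
#'
#' @return A 3 x 3 row-stochastic matrix (nearest-first state order).
#' @export
default_move_matrix <- function() {
  m <- matrix(c(0.8, 0.2, 0.0,
                0.1, 0.8, 0.1,
                0.0, 0.2, 0.8), nrow = 3L, byrow = TRUE,
              dimnames = list(bystander_states(), bystander_states()))
  m
}

#' Sample one action window's intervention flags
#'
#' @param model A [participant_model()].
#' @param a Action name, one of [agent_actions()].
#' @return An [intervention_flags()] list, plus element `y` (0/1 any-response
#'   indicator).
#' @export
sample_response <- function(model, a) {
  stopifnot(inherits(model, "participant_model"), a %in% agent_actions())
  p <- inv_logit(model$u + model$weights[[a]])
  y <- stats::runif(1) < p
  if (!y) {
    fl <- intervention_flags(FALSE, FALSE)
  } else {
    repeat {
      v <- stats::runif(1) < model$p_verbal_given_response
      ph <- stats::runif(1) < model$p_physical_given_response
      if (v || ph) break
    }
    fl <- intervention_flags(v, ph)
  }
  fl$y <- as.integer(y)
  fl
}

#' Advance the participant's proxemic state by one window
#'
#' Samples the next band from the movement chain's row for the current band;
#' if the participant responded this window, the approach bonus first shifts
#' probability mass one band nearer (each unit of mass at a non-nearest band
#' moves nearer with probability `approach_bonus`).
#'
#' @param model A [participant_model()].
#' @param s Current state name.
#' @param responded Logical: did the participant intervene this window?
#' @return Next state name.
#' @export
step_distance_state <- function(model, s, responded = FALSE) {
  stopifnot(inherits(model, "participant_model"), s %in% bystander_states())
  p <- model$move[s, ]
  if (isTRUE(responded) && model$approach_bonus > 0) {
    b <- model$approach_bonus
    shift <- p[2:3] * b
    p[1:2] <- p[1:2] + shift
    p[2:3] <- p[2:3] - shift
  }
  bystander_states()[sample.int(3L, 1L, prob = p)]
}

#' Generate a per-trial action-effect dataset
#'
#' Draws synthetic per-trial binary responses directly from the Bernoulli
#' logistic action-effect model, bypassing the RL loop: subject effects
#' `u_k ~ Normal(0, sigma_u)`, one action per trial, response probability
#' `inv_logit(u + b[action])`. This is the generator used for
#' parameter-recovery calibration of the simplex-constrained model.
#'
#' @param n_participants Number of subjects (default 45).
#' @param N Trials per subject (default 13).
#' @param weights Length-3 simplex weights `(b_vl, b_pl, b_bu)`.
#' @param sigma_u SD of the subject effects (default 1).
#' @param action_assignment Either `"random"` (uniform i.i.d. actions), a
#'   single action name (fixed design), or a character vector of
#'   `n_participants * N` action names (e.g. taken from a study run).
#' @return Data frame with columns `id`, `trial`, `action`, `vl`, `pl`, `bu`,
#'   `y`; `id` in blocks of `N`, exactly one of `vl`/`pl`/`bu` equal to 1 per
#'   row.
#' @export
generate_action_effect_dataset <- function(n_participants = 45L, N = 13L,
                                           weights = c(0.59, 0.29, 0.12),
                                           sigma_u = 1,
                                           action_assignment = "random") {
  stopifnot(n_participants >= 1L, N >= 1L, sigma_u >= 0)
  n <- n_participants * N
  actions <- agent_actions()
  if (identical(action_assignment, "random")) {
    a <- actions[sample.int(3L, n, replace = TRUE)]
  } else if (length(action_assignment) == 1L &&
             action_assignment %in% actions) {
    a <- rep(action_assignment, n)
  } else {
    stopifnot(length(action_assignment) == n,
              all(action_assignment %in% actions))
    a <- action_assignment
  }
  w <- stats::setNames(weights, actions)
  u <- stats::rnorm(n_participants, 0, sigma_u)
  id <- rep(seq_len(n_participants), each = N)
  p <- inv_logit(u[id] + unname(w[a]))
  y <- as.integer(stats::runif(n) < p)
  data.frame(id = id, trial = rep(seq_len(N), times = n_participants),
             action = a,
             vl = as.integer(a == actions[1L]),
             pl = as.integer(a == actions[2L]),
             bu = as.integer(a == actions[3L]),
             y = y)
}

#' Specification of a Beta-Binomial response-count generator
#'
#' @param n_participants Number of subjects (default 45).
#' @param N Trials per subject (default 13).
#' @param beta0,beta1 Intercept and slope of the logistic mean model
#'   `p_i = inv_logit(beta0 + beta1 * proprandom_i)`.
#' @param phi Positive dispersion scale; the per-subject response probability
#'   is drawn from `Beta(p_i * phi, (1 - p_i) * phi)`.
#' @param proprandom_values Numeric vector in [0, 1] of length
#'   `n_participants` (the covariate).
#' @return An object of class `betabinom_gen_spec`.
#' @export
betabinom_gen_spec <- function(n_participants = 45L, N = 13L,
                               beta0 = 1.34, beta1 = -1.45, phi = 1.17,
                               proprandom_values =
                                 rep(c(1, 0.66, 0.33), each = 15L)) {
  if (phi <= 0) stop("betabinom_gen_spec: phi must be > 0", call. = FALSE)
  stopifnot(N >= 1L, length(proprandom_values) == n_participants,
            all(proprandom_values >= 0), all(proprandom_values <= 1))
  structure(list(n_participants = as.integer(n_participants), N = as.integer(N),
                 beta0 = beta0, beta1 = beta1, phi = phi,
                 proprandom_values = proprandom_values),
            class = "betabinom_gen_spec")
}

#' Generate per-participant intervention counts from the Beta-Binomial model
#'
#' For each participant draw a response probability from a Beta with mean
#' `inv_logit(beta0 + beta1 * proprandom)` and scale `phi`, then the
#' intervention count `resp` from `Binomial(N, p)`. This is the generative
#' counterpart of the count-level analysis models and is used for their
#' parameter-recovery calibration.
#'
#' @param spec A [betabinom_gen_spec()].
#' @return Data frame with columns `id`, `proprandom`, `resp`, `N`.
#' @export
generate_beta_binomial_dataset <- function(spec = betabinom_gen_spec()) {
  stopifnot(inherits(spec, "betabinom_gen_spec"))
  x <- spec$proprandom_values
  p_mean <- inv_logit(spec$beta0 + spec$beta1 * x)
  theta <- stats::rbeta(spec$n_participants, p_mean * spec$phi,
                        (1 - p_mean) * spec$phi)
  resp <- stats::rbinom(spec$n_participants, spec$N, theta)
  data.frame(id = seq_len(spec$n_participants), proprandom = x,
             resp = resp, N = spec$N)
}
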