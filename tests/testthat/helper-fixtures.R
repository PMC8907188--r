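# Shared fixtures for the suite.

# Participant that always (u = +20) or never (u = -20) responds.
saturated_participant <- function(u) {
  participant_model(u = u)
}

# Participant pinned to one proxemic band (identity movement, no bonus).
pinned_participant <- function(u, state = "Passive") {
  participant_model(u = u, move = diag(3), approach_bonus = 0)
}

# Short MCMC config sized for unit tests.
test_mcmc <- function(iterations = 1000L, chains = 2L, seed = 1L) {
  mcmc_config(iterations = iterations, chains = chains, seed = seed)
}

# Independent brute-force Watkins' Q(lambda) recurrence: replays an episode
# of transitions (with per-step greedy flags for the *next* action) from
# first principles, never calling the package's update functions.
brute_force_q_lambda <- function(episode, params, q0 = NULL) {
  states <- c("Intervention", "Active", "Passive")
  actions <- c("VictimLookAt", "PerpLookAt", "BystandersUtter")
  q <- if (is.null(q0)) matrix(0, 3, 3, dimnames = list(states, actions))
       else q0
  e <- matrix(0, 3, 3, dimnames = list(states, actions))
  for (t in seq_along(episode)) {
    tr <- episode[[t]]
    target <- if (is.null(tr$s_next)) tr$r
              else tr$r + params$gamma * max(q[tr$s_next, ])
    delta <- target - q[tr$s, tr$a]
    e[tr$s, tr$a] <- e[tr$s, tr$a] + 1
    for (si in states) for (ai in actions)
      q[si, ai] <- q[si, ai] + params$alpha * delta * e[si, ai]
    if (!is.null(tr$next_greedy)) {
      if (tr$next_greedy) e <- e * params$gamma * params$lam
      else e[] <- 0
    }
  }
  q
}

# Random episode generator over the full state/action space.
random_episode <- function(n_steps) {
  states <- c("Intervention", "Active", "Passive")
  actions <- c("VictimLookAt", "PerpLookAt", "BystandersUtter")
  lapply(seq_len(n_steps), function(t) list(
    s = sample(states, 1), a = sample(actions, 1),
    r = sample(c(-0.1, 1, 2), 1),
    s_next = if (t == n_steps) NULL else sample(states, 1),
    next_greedy = if (t == n_steps) NULL else runif(1) < 0.7))
}
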