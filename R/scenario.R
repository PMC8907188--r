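#' Bystander proxemic states
#'
#' The three distance bands between the participant and the arguing characters
#' that define the reinforcement-learning state: `Intervention` (within arm's
#' reach, < 0.5 m), `Active` (close but keeping a safety distance, 0.5-1 m)
#' and `Passive` (staying away, >= 1 m).
#'
#' @return Character vector of the three state names, ordered from nearest to
#'   farthest.
#' @export
bystander_states <- function() {
  c("Intervention", "Active", "Passive")
}

#' Virtual-character actions
#'
#' The three actions the agent can trigger: the victim turning to look at the
#' participant (`VictimLookAt`), the perpetrator doing the same (`PerpLookAt`),
#' or one of the virtual bystanders saying an encouraging utterance out loud
#' (`BystandersUtter`).
#'
#' @return Character vector of the three action names.
#' @export
agent_actions <- function() {
  c("VictimLookAt", "PerpLookAt", "BystandersUtter")
}

#' Scenario configuration
#'
#' Timing and proxemics constants for one confrontation. Defaults reproduce the
#' study design: the first action 4 s after the confrontation starts, one
#' action every 10 s thereafter, 13 action slots within a 130 s confrontation,
#' and distance bands cut at 0.5 m and 1 m.
#'
#' @param n_slots Number of action opportunities (>= 1).
#' @param first_action_s Seconds from confrontation onset to the first action.
#' @param interval_s Seconds between consecutive actions.
#' @param confrontation_s Total confrontation length in seconds.
#' @param near_threshold_m Distance (m) below which the participant can reach
#'   the characters (`Intervention` band).
#' @param far_threshold_m Distance (m) beyond which the participant is
#'   `Passive`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_slots = 13L, first_action_s = 4, interval_s = 10,
                            confrontation_s = 130, near_threshold_m = 0.5,
                            far_threshold_m = 1.0) {
  cfg <- structure(
    list(n_slots = as.integer(n_slots), first_action_s = first_action_s,
         interval_s = interval_s, confrontation_s = confrontation_s,
         near_threshold_m = near_threshold_m, far_threshold_m = far_threshold_m),
    class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_slots < 1L)
    stop("scenario_config: n_slots must be >= 1", call. = FALSE)
  if (!(cfg$near_threshold_m > 0 && cfg$near_threshold_m < cfg$far_threshold_m))
    stop("scenario_config: need 0 < near_threshold_m < far_threshold_m",
         call. = FALSE)
  last <- cfg$first_action_s + (cfg$n_slots - 1L) * cfg$interval_s
  if (last > cfg$confrontation_s)
    stop(sprintf(
      "scenario_config: last action at %gs exceeds confrontation length %gs",
      last, cfg$confrontation_s), call. = FALSE)
  invisible(cfg)
}

#' Number of action slots that fit a confrontation
#'
#' Derives how many actions fit when only the timing constants are known:
#' the largest `n` with `first_action_s + (n - 1) * interval_s <=
#' confrontation_s`.
#'
#' @inheritParams scenario_config
#' @return Integer slot count.
#' @export
derive_n_slots <- function(first_action_s = 4, interval_s = 10,
                           confrontation_s = 130) {
  if (first_action_s > confrontation_s) return(0L)
  as.integer(floor((confrontation_s - first_action_s) / interval_s)) + 1L
}

#' Classify a participant distance into a proxemic state
#'
#' Half-open bands (lower-inclusive): `[0, near)` is `Intervention`,
#' `[near, far)` is `Active`, `[far, Inf)` is `Passive`. A distance exactly on
#' a boundary is assigned to the farther band.
#'
#' @param distance_m Nonnegative finite distance in metres (vectorised).
#' @param config A [scenario_config()].
#' @return Character vector of state names.
#' @examples
#' classify_state(c(0.3, 0.75, 2.0))
#' @export
classify_state <- function(distance_m, config = scenario_config()) {
  if (length(distance_m) == 0L) return(character(0))
  if (any(!is.finite(distance_m)) || any(distance_m < 0))
    stop("classify_state: distance must be finite and >= 0", call. = FALSE)
  states <- bystander_states()
  ifelse(distance_m < config$near_threshold_m, states[1L],
         ifelse(distance_m < config$far_threshold_m, states[2L], states[3L]))
}

#' Intervention flags for one action window
#'
#' @param verbal Logical: did the participant intervene verbally?
#' @param physical Logical: did the participant intervene physically?
#' @return A list with elements `verbal` and `physical`.
#' @export
intervention_flags <- function(verbal = FALSE, physical = FALSE) {
  stopifnot(is.logical(verbal), is.logical(physical),
            length(verbal) == 1L, length(physical) == 1L,
            !is.na(verbal), !is.na(physical))
  list(verbal = verbal, physical = physical)
}

#' Reward for one action window
#'
#' 1 point per intervention type observed during the 10 s window (verbal,
#' physical), so a window with both is worth 2; a window with no intervention
#' returns -0.1, a small penalty that encourages the agent to try actions it
#' has not tried before.
#'
#' @param flags An [intervention_flags()] list (or anything with logical
#'   `verbal` and `physical` elements).
#' @return Numeric scalar in `{-0.1, 1, 2}`.
#' @export
compute_reward <- function(flags) {
  v <- isTRUE(flags$verbal)
  p <- isTRUE(flags$physical)
  if (!v && !p) return(-0.1)
  as.numeric(v + p)
}

#' Timeline of action slots
#'
#' @param config A [scenario_config()].
#' @return Numeric vector of `n_slots` strictly increasing times (seconds from
#'   confrontation onset).
#' @examples
#' action_schedule(scenario_config())  # 4, 14, ..., 124
#' @export
action_schedule <- function(config = scenario_config()) {
  validate_scenario_config(config)
  config$first_action_s + config$interval_s * (seq_len(config$n_slots) - 1L)
}

#' The bystander utterance list
#'
#' The 12 encouraging utterances virtual bystanders can say, in their scripted
#' order (some expressions repeat because two voice actors recorded them).
#' Shipped as a plain-text resource, one utterance per line.
#'
#' @return Character vector of length 12.
#' @export
utterance_list <- function() {
  path <- system.file("extdata", "utterances.txt", package = "bystanderRL",
                      mustWork = TRUE)
  x <- readLines(path, encoding = "UTF-8")
  stopifnot(length(x) == 12L)
  x
}

#' Sequential utterance cursor
#'
#' Utterances are served sequentially; because a session can hold more
#' `BystandersUtter` actions (up to 13) than there are utterances (12), the
#' cursor wraps to the start of the list when exhausted.
#'
#' @param utterances Character vector of utterances (default the shipped list).
#' @param next_index Zero-based index of the next utterance to serve.
#' @return An object of class `utterance_cursor`.
#' @export
utterance_cursor <- function(utterances = utterance_list(), next_index = 0L) {
  stopifnot(length(utterances) >= 1L, next_index >= 0L)
  structure(list(utterances = utterances, next_index = as.integer(next_index)),
            class = "utterance_cursor")
}

#' Serve the next utterance
#'
#' @param cursor An [utterance_cursor()].
#' @return List with `utterance` (string), `index` (zero-based index served,
#'   after wrap-around) and `cursor` (updated cursor).
#' @export
next_utterance <- function(cursor) {
  stopifnot(inherits(cursor, "utterance_cursor"))
  k <- cursor$next_index %% length(cursor$utterances)
  cursor$next_index <- cursor$next_index + 1L
  list(utterance = cursor$utterances[k + 1L], index = k, cursor = cursor)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$n_slots, "action slots at",
      paste0(action_schedule(x), collapse = ", "), "s;",
      "bands <", x$near_threshold_m, "m /<", x$far_threshold_m, "m\n")
  invisible(x)
}
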