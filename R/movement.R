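movement_states <- c("stand", "walk", "jog", "sprint", "brake")

#' Semi-Markov movement profile for the match simulator
#'
#' Describes the stochastic locomotion model generating synthetic 10 Hz
#' speed traces: five movement states (standing, walking, jogging,
#' sprinting, and contact braking), mean dwell times, per-state target-speed
#' distributions, a state transition matrix, and a two-component
#' (mild/hard) mixture for the linear speed ramps between states. The
#' sprint target speed is expressed relative to the athlete's individual
#' sprint-entry threshold so that every athlete accrues high-speed
#' distance. Defaults are calibrated so that a full simulated study
#' reproduces the zone-distance profile of international women's sevens
#' match data; see the methods vignette.
#'
#' @param mean_dwell_s Named numeric: mean dwell time per state, seconds.
#' @param speed_mean_mps,speed_sd_mps Named numeric: target-speed
#'   distribution per state, m/s. For `sprint` the mean is an offset added
#'   to the athlete's sprint-entry threshold.
#' @param transition 5x5 row-stochastic matrix of state transition
#'   probabilities (rows/cols in `stand, walk, jog, sprint, brake` order;
#'   diagonal 0).
#' @param ramp_mild_mps2,ramp_hard_mps2 Length-2 ranges (min, max) for the
#'   mild (< 2 m/s^2) and hard (> 2 m/s^2) ramp-magnitude components.
#' @param hard_ramp_prob_up,hard_ramp_prob_down Mixing weight of the hard
#'   component for accelerating and decelerating ramps (brake entries are
#'   always hard).
#' @param contact_rate_per_min Contact events per on-field minute (used as
#'   the default rate by [simulate_contacts()]).
#' @param p_full_match Probability an athlete plays the full match.
#' @param partial_range_min Range (min, max) in minutes of play for a
#'   substituted athlete; uniform.
#' @return A list of class `movement_profile`.
#' @export
movement_profile <- function(
    mean_dwell_s = c(stand = 10, walk = 12, jog = 13, sprint = 3.9,
                     brake = 2),
    speed_mean_mps = c(stand = 0, walk = 1.0, jog = 2.75, sprint = 0.33,
                       brake = 0.25),
    speed_sd_mps = c(stand = 0, walk = 0.12, jog = 0.3, sprint = 0.15,
                     brake = 0.08),
    transition = default_transition_matrix(),
    ramp_mild_mps2 = c(1.0, 1.9),
    ramp_hard_mps2 = c(2.4, 4.2),
    hard_ramp_prob_up = 0.48,
    hard_ramp_prob_down = 0.32,
    contact_rate_per_min = 4 / 11.8,
    p_full_match = 0.52,
    partial_range_min = c(6, 14)) {
  p <- structure(
    list(
      mean_dwell_s = mean_dwell_s[movement_states],
      speed_mean_mps = speed_mean_mps[movement_states],
      speed_sd_mps = speed_sd_mps[movement_states],
      transition = transition,
      ramp_mild_mps2 = ramp_mild_mps2,
      ramp_hard_mps2 = ramp_hard_mps2,
      hard_ramp_prob_up = hard_ramp_prob_up,
      hard_ramp_prob_down = hard_ramp_prob_down,
      contact_rate_per_min = contact_rate_per_min,
      p_full_match = p_full_match,
      partial_range_min = partial_range_min
    ),
    class = "movement_profile"
  )
  validate_movement_profile(p)
}

default_transition_matrix <- function() {
  m <- rbind(
    stand  = c(0,    0.75, 0.25, 0,    0),
    walk   = c(0.43, 0,    0.49, 0.04, 0.04),
    jog    = c(0.12, 0.515, 0,    0.215, 0.15),
    sprint = c(0,    0.10, 0.70, 0,    0.20),
    brake  = c(0.50, 0.30, 0.20, 0,    0)
  )
  colnames(m) <- movement_states
  m
}

validate_movement_profile <- function(p) {
  stopifnot(inherits(p, "movement_profile"))
  if (any(is.na(p$mean_dwell_s)) || any(p$mean_dwell_s <= 0)) {
    stop_invalid("all state dwell times must be > 0")
  }
  if (any(is.na(p$speed_mean_mps)) || any(p$speed_mean_mps < 0)) {
    stop_invalid("state target speeds must be >= 0")
  }
  tm <- p$transition
  if (!is.matrix(tm) || any(dim(tm) != 5L) ||
      any(abs(rowSums(tm) - 1) > 1e-8) || any(tm < 0)) {
    stop_invalid("transition must be a 5x5 row-stochastic matrix")
  }
  for (r in list(p$ramp_mild_mps2, p$ramp_hard_mps2)) {
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop_invalid("ramp ranges must be positive (min, max) pairs")
    }
  }
  for (w in c(p$hard_ramp_prob_up, p$hard_ramp_prob_down)) {
    check_number(w, "hard ramp weight", lower = 0, upper = 1)
  }
  check_number(p$contact_rate_per_min, "contact_rate_per_min", lower = 0)
  check_number(p$p_full_match, "p_full_match", lower = 0, upper = 1)
  if (length(p$partial_range_min) != 2L || any(p$partial_range_min <= 0) ||
      p$partial_range_min[1] > p$partial_range_min[2]) {
    stop_invalid("partial_range_min must be a positive (min, max) pair")
  }
  p
}
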