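#' Construct a 10 Hz speed trace
#'
#' A `speed_trace` is the unit of raw kinematic data: one athlete's speed
#' series for one match, sampled on a uniform clock, with an on-field flag
#' (players are substituted on and off) and a period label (`H1`, `HT`, `H2`).
#'
#' @param time_s Sample times in seconds, uniformly spaced at
#'   `1 / sample_rate_hz`.
#' @param speed_mps Non-negative speed in metres per second, one per sample.
#' @param on_field Logical per sample; `FALSE` while substituted off.
#' @param period Character per sample, one of `"H1"`, `"HT"`, `"H2"`.
#' @param athlete_id,match_id Identifiers attached as attributes.
#' @param sample_rate_hz Sampling rate in hertz; GNSS units report at 10.
#'
#' @return A tibble of class `speed_trace` with columns `time_s`, `speed_mps`,
#'   `on_field`, `period` and attributes `athlete_id`, `match_id`,
#'   `sample_rate_hz`.
#' @export
speed_trace <- function(time_s, speed_mps, on_field, period,
                        athlete_id = NA_character_, match_id = NA_character_,
                        sample_rate_hz = 10) {
  out <- tibble::new_tibble(
    list(
      time_s = as.numeric(time_s),
      speed_mps = as.numeric(speed_mps),
      on_field = as.logical(on_field),
      period = as.character(period)
    ),
    nrow = length(time_s)
  )
  attr(out, "athlete_id") <- as.character(athlete_id)
  attr(out, "match_id") <- as.character(match_id)
  attr(out, "sample_rate_hz") <- as.numeric(sample_rate_hz)
  class(out) <- c("speed_trace", class(out))
  out <- validate_speed_trace(out)
  attr(out, "validated") <- TRUE
  out
}

# cheap re-check for internal hot paths: a trace built by speed_trace()
# has already passed full validation
check_speed_trace <- function(trace) {
  if (isTRUE(attr(trace, "validated"))) trace else validate_speed_trace(trace)
}

#' Validate a speed trace
#'
#' Checks the structural invariants: non-negative speeds, strictly increasing
#' uniformly spaced time (tolerance 1e-9 s), equal-length columns, known
#' period labels.
#'
#' @param trace A [speed_trace()].
#' @return The trace, invisibly usable; errors on violation.
#' @export
validate_speed_trace <- function(trace) {
  if (!all(c("time_s", "speed_mps", "on_field", "period") %in% names(trace))) {
    stop_invalid("trace must have columns time_s, speed_mps, on_field, period")
  }
  if (nrow(trace) < 2L) stop_invalid("trace must contain at least 2 samples")
  if (any(!is.finite(trace$speed_mps)) || any(trace$speed_mps < 0)) {
    stop_invalid("speeds must be finite and >= 0")
  }
  hz <- trace_sample_rate(trace)
  dt <- diff(trace$time_s)
  if (any(dt <= 0) || any(abs(dt - 1 / hz) > 1e-9)) {
    stop_invalid(sprintf(
      "time_s must be strictly increasing with spacing 1/%g s", hz
    ))
  }
  if (!all(trace$period %in% c("H1", "HT", "H2"))) {
    stop_invalid("period labels must be H1, HT or H2")
  }
  if (any(is.na(trace$on_field))) stop_invalid("on_field must be TRUE/FALSE")
  trace
}

trace_sample_rate <- function(trace) {
  hz <- attr(trace, "sample_rate_hz")
  if (is.null(hz)) 10 else hz
}

#' @export
print.speed_trace <- function(x, ...) {
  hz <- trace_sample_rate(x)
  cat(sprintf(
    "<speed_trace> athlete %s, match %s: %d samples @ %g Hz (%.1f s), %.1f%% on-field\n",
    attr(x, "athlete_id"), attr(x, "match_id"), nrow(x), hz,
    nrow(x) / hz, 100 * mean(x$on_field)
  ))
  NextMethod()
}

# samples that count toward play: on the field and not during halftime
play_mask <- function(trace) {
  trace$on_field & trace$period != "HT"
}
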