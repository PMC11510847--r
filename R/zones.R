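#' Speed and acceleration zone thresholds
#'
#' The twelve movement zones are the cross of three speed zones and four
#' acceleration types. Speed zones: low speed (walking, `LS`) below
#' `walk_upper_mps`; moderate speed (running, `MS`) up to the athlete's
#' individual sprint-entry threshold; high speed (sprinting, `HS`) at and
#' above it. Acceleration types split at `accel_threshold_mps2`: `LA`/`HA`
#' for mild/hard positive acceleration, `LD`/`HD` for mild/hard deceleration.
#' Zero acceleration (constant speed) is counted as mild deceleration (`LD`);
#' see the package vignette for the rationale.
#'
#' @param sprint_entry_mps Athlete's sprint-entry speed in m/s, from the
#'   0-10 m split of a maximal 40 m sprint; must exceed `walk_upper_mps`.
#' @param walk_upper_mps Upper bound of the walking zone in m/s (default 1.5).
#' @param accel_threshold_mps2 Magnitude in m/s^2 separating mild from hard
#'   acceleration/deceleration (default 2).
#' @return A list of class `zone_thresholds`.
#' @export
zone_thresholds <- function(sprint_entry_mps, walk_upper_mps = 1.5,
                            accel_threshold_mps2 = 2) {
  check_number(sprint_entry_mps, "sprint_entry_mps")
  check_number(walk_upper_mps, "walk_upper_mps", lower = 0,
               allow_equal_lower = FALSE)
  check_number(accel_threshold_mps2, "accel_threshold_mps2", lower = 0,
               allow_equal_lower = FALSE)
  if (sprint_entry_mps <= walk_upper_mps) {
    stop_invalid("sprint_entry_mps must exceed walk_upper_mps")
  }
  structure(
    list(
      walk_upper_mps = walk_upper_mps,
      sprint_entry_mps = sprint_entry_mps,
      accel_threshold_mps2 = accel_threshold_mps2
    ),
    class = "zone_thresholds"
  )
}

#' Sprint-entry threshold from a timed sprint split
#'
#' Converts the 0-10 m split of a maximal 40 m sprint into the athlete's
#' individual sprint-entry speed, taken as the mean velocity over the split.
#'
#' @param split_distance_m Split length in metres (10 by convention).
#' @param split_time_s Time over the split in seconds.
#' @return Sprint-entry speed in m/s.
#' @export
#' @examples
#' sprint_threshold_from_split(10, 2.0) # 5 m/s
sprint_threshold_from_split <- function(split_distance_m, split_time_s) {
  check_number(split_distance_m, "split_distance_m", lower = 0,
               allow_equal_lower = FALSE)
  check_number(split_time_s, "split_time_s", lower = 0,
               allow_equal_lower = FALSE)
  v <- split_distance_m / split_time_s
  if (v <= 1.5) {
    abort(
      sprintf(
        "split velocity %.3f m/s does not exceed the 1.5 m/s walk boundary; unusable as a sprint-entry threshold",
        v
      ),
      class = c("threshold_unusable", "sevensload_error")
    )
  }
  v
}

#' Acceleration series from a speed trace
#'
#' Acceleration is the first derivative of the GNSS speed signal, computed as
#' a backward first difference scaled by the sample rate. The first sample,
#' having no predecessor, is assigned 0. Optionally the speed is first
#' smoothed with a centred moving average (odd window, edges truncated).
#'
#' @param trace A [speed_trace()].
#' @param smoothing_window Odd integer >= 1; 1 (default) means no smoothing.
#' @return Numeric vector of accelerations in m/s^2, aligned with the trace.
#' @export
compute_acceleration <- function(trace, smoothing_window = 1) {
  check_speed_trace(trace)
  w <- smoothing_window
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w) ||
      w %% 2 == 0) {
    stop_invalid("smoothing_window must be an odd integer >= 1")
  }
  v <- trace$speed_mps
  if (w > 1) v <- moving_average(v, w)
  hz <- trace_sample_rate(trace)
  c(0, diff(v) * hz)
}

# centred moving average with edge truncation (shorter windows at the ends)
moving_average <- function(x, w) {
  h <- (w - 1L) / 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

speed_zone_levels <- c("LS", "MS", "HS")
accel_type_levels <- c("LA", "HA", "LD", "HD")

#' Assign speed zone and acceleration type
#'
#' Maps each (speed, acceleration) pair to exactly one of the twelve zones.
#' Speed zones are half-open, lower-inclusive: `[0, walk_upper)` is `LS`,
#' `[walk_upper, sprint_entry)` is `MS`, `[sprint_entry, Inf)` is `HS`.
#' Acceleration types: `HA` above the threshold, `LA` in `(0, threshold]`,
#' `LD` in `[-threshold, 0]` (constant speed counts as mild deceleration),
#' `HD` below `-threshold`.
#'
#' @param speed_mps,accel_mps2 Numeric vectors of equal length.
#' @param thresholds A [zone_thresholds()].
#' @return A tibble with factor columns `speed_zone` (`LS`/`MS`/`HS`) and
#'   `accel_type` (`LA`/`HA`/`LD`/`HD`).
#' @export
assign_zone <- function(speed_mps, accel_mps2, thresholds) {
  codes <- zone_codes(speed_mps, accel_mps2, thresholds)
  tibble(
    speed_zone = factor(speed_zone_levels[codes$speed], levels = speed_zone_levels),
    accel_type = factor(accel_type_levels[codes$accel], levels = accel_type_levels)
  )
}

# integer zone codes (speed 1:3 = LS/MS/HS, accel 1:4 = LA/HA/LD/HD);
# the arithmetic encodes: positive accel -> LA/HA, a <= 0 -> LD/HD,
# magnitude above the threshold selects the hard variant
zone_codes <- function(speed_mps, accel_mps2, thresholds) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  if (length(speed_mps) != length(accel_mps2)) {
    stop_invalid("speed_mps and accel_mps2 must have equal length")
  }
  if (any(speed_mps < 0)) stop_invalid("speeds must be >= 0")
  sz <- findInterval(
    speed_mps,
    c(0, thresholds$walk_upper_mps, thresholds$sprint_entry_mps)
  )
  at <- 1L + (abs(accel_mps2) > thresholds$accel_threshold_mps2) +
    2L * (accel_mps2 <= 0)
  list(speed = sz, accel = at)
}

#' Names of the twelve zone-distance cells
#'
#' Column order used throughout: speed zone major (`LS`, `MS`, `HS`), then
#' acceleration type (`LA`, `HA`, `LD`, `HD`), joined with an underscore.
#' @return Character vector of 12 cell names, `LS_LA` through `HS_HD`.
#' @export
zone_cell_names <- function() {
  as.vector(t(outer(speed_zone_levels, accel_type_levels, paste, sep = "_")))
}

#' Accumulate distance into the twelve movement zones
#'
#' Integrates per-sample distance (`speed * dt`) into the zone of that
#' sample, over on-field, non-halftime samples only. Halftime is excluded
#' from both zone distances and playing time even though players remain on
#' the field. Playing time is the count of contributing samples over the
#' sample rate.
#'
#' @param trace A [speed_trace()].
#' @param accel Acceleration series from [compute_acceleration()], aligned
#'   with the trace.
#' @param thresholds A [zone_thresholds()].
#' @return A list of class `zone_distances`: `cells` (named numeric of the
#'   12 distances in metres, in [zone_cell_names()] order), `total_m`, and
#'   `playing_time_min`.
#' @export
accumulate_zone_distances <- function(trace, accel, thresholds) {
  check_speed_trace(trace)
  if (length(accel) != nrow(trace)) {
    stop_invalid("accel must be aligned with the trace (equal length)")
  }
  hz <- trace_sample_rate(trace)
  keep <- play_mask(trace)
  v <- trace$speed_mps[keep]
  codes <- zone_codes(v, accel[keep], thresholds)
  idx <- (codes$speed - 1L) * 4L + codes$accel
  d <- v / hz
  cells <- setNames(numeric(12L), zone_cell_names())
  if (length(d) > 0) {
    rs <- rowsum(d, idx)
    cells[as.integer(rownames(rs))] <- rs[, 1]
  }
  structure(
    list(
      cells = cells,
      total_m = sum(d),
      playing_time_min = sum(keep) / (60 * hz)
    ),
    class = "zone_distances"
  )
}

#' @export
print.zone_distances <- function(x, ...) {
  cat(sprintf(
    "<zone_distances> total %.1f m over %.2f min on-field\n",
    x$total_m, x$playing_time_min
  ))
  m <- matrix(x$cells, nrow = 3, byrow = TRUE,
              dimnames = list(speed_zone_levels, accel_type_levels))
  print(round(m, 2))
  invisible(x)
}

#' Comparator acceleration summaries from the literature
#'
#' Computes the three simpler acceleration-processing outputs that the
#' twelve-zone grid generalises, over the same on-field, non-halftime
#' samples: (i) total distance at hard acceleration or deceleration
#' magnitude (all values taken as positive); (ii) the quotient of hard
#' acceleration distance over hard deceleration distance; (iii) the four
#' acceleration-type bins with no speed split.
#'
#' @inheritParams accumulate_zone_distances
#' @return A list with `total_accel_distance_m`, `accel_decel_ratio`
#'   (`NA` with `ratio_defined = FALSE` when the deceleration distance is
#'   zero), and `four_bin` (named numeric: `LA`, `HA`, `LD`, `HD` metres).
#' @export
comparator_summaries <- function(trace, accel, thresholds) {
  zd <- accumulate_zone_distances(trace, accel, thresholds)
  m <- matrix(zd$cells, nrow = 3, byrow = TRUE,
              dimnames = list(speed_zone_levels, accel_type_levels))
  four_bin <- colSums(m)
  acc <- four_bin[["HA"]]
  dec <- four_bin[["HD"]]
  ratio_defined <- dec > 0
  list(
    total_accel_distance_m = acc + dec,
    accel_decel_ratio = if (ratio_defined) acc / dec else NA_real_,
    ratio_defined = ratio_defined,
    four_bin = four_bin
  )
}
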