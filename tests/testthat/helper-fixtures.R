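# shared fixtures, all built in code

# a minimal on-field trace from an explicit speed vector (H1, all on field)
trace_from_speeds <- function(speeds, hz = 10, on_field = TRUE,
                              period = "H1") {
  n <- length(speeds)
  speed_trace(
    time_s = (seq_len(n) - 1) / hz,
    speed_mps = speeds,
    on_field = rep_len(on_field, n),
    period = rep_len(period, n),
    athlete_id = "T01", match_id = "MT1", sample_rate_hz = hz
  )
}

# a random but structurally valid trace for property tests: mixed periods,
# substitution spans, speeds with occasional hard jumps kept within bounds
random_trace <- function(n = 400, seed = 1) {
  withr::with_seed(seed, {
    speeds <- pmax(0, cumsum(rnorm(n, 0, 0.3)) + runif(1, 0, 3))
    per <- rep(c("H1", "HT", "H2"), length.out = 3)[
      findInterval((seq_len(n) - 1) / n, c(0, 0.45, 0.55)) ]
    onf <- runif(n) > 0.15
    speeds[!onf] <- 0
    speed_trace(
      time_s = (seq_len(n) - 1) / 10,
      speed_mps = speeds, on_field = onf, period = per,
      athlete_id = "R01", match_id = "MR1"
    )
  })
}

# per-sample reference implementation of the 12-zone accumulation: the
# independent oracle the vectorised path is checked against
zone_loop_oracle <- function(trace, accel, thresholds) {
  cells <- setNames(numeric(12), zone_cell_names())
  hz <- attr(trace, "sample_rate_hz")
  n_play <- 0L
  for (i in seq_len(nrow(trace))) {
    if (!trace$on_field[i] || trace$period[i] == "HT") next
    n_play <- n_play + 1L
    v <- trace$speed_mps[i]
    a <- accel[i]
    sz <- if (v < thresholds$walk_upper_mps) "LS"
          else if (v < thresholds$sprint_entry_mps) "MS" else "HS"
    at <- if (a > thresholds$accel_threshold_mps2) "HA"
          else if (a > 0) "LA"
          else if (a >= -thresholds$accel_threshold_mps2) "LD" else "HD"
    key <- paste(sz, at, sep = "_")
    cells[key] <- cells[key] + v / hz
  }
  list(cells = cells, total_m = sum(cells),
       playing_time_min = n_play / (60 * hz))
}

# small simulated study shared across test files (computed once per run)
.test_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.test_cache$small)) {
    .test_cache$small <- simulate_study(
      study_config(n_matches = 12, n_athletes = 19, fielded_per_match = 12),
      seed = 42
    )
  }
  .test_cache$small
}

small_complete <- function() {
  if (is.null(.test_cache$small_complete)) {
    .test_cache$small_complete <- drop_incomplete(small_study(), quiet = TRUE)
  }
  .test_cache$small_complete
}

small_fit <- function() {
  if (is.null(.test_cache$small_fit)) {
    .test_cache$small_fit <- suppressWarnings(
      fit_workload_model(small_complete())
    )
  }
  .test_cache$small_fit
}

# zero-noise study (no athlete or residual noise, no game shifts, exact
# latent RPE, no missingness): the workload model is exactly identifiable
zero_noise_truth <- function() {
  ground_truth_params(
    sigma_u = 0, sigma_e = 0,
    game_effect = c(`1` = 0, `2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0),
    rpe_missing_prob = 0
  )
}

zero_noise_study <- function() {
  if (is.null(.test_cache$zero)) {
    cfg <- study_config(n_matches = 8, truth = zero_noise_truth())
    ds <- simulate_study(cfg, seed = 7, exact_rpe = TRUE)
    roster <- attr(ds, "roster")
    scl <- zero_noise_truth()$scaling
    scl$center[["mass_kg"]] <- mean(roster$mass_kg)
    fit <- suppressWarnings(suppressMessages(
      fit_workload_model(ds, model_spec(scaling = scl))
    ))
    .test_cache$zero <- list(dataset = ds, fit = fit, scaling = scl)
  }
  .test_cache$zero
}
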