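#' Simulate an athlete roster
#'
#' Draws a squad of athlete profiles: body mass, individual sprint-entry
#' threshold, and the athlete's latent random intercept (the `u_j` of the
#' workload model).
#'
#' @param n_athletes Number of athletes (>= 2; a mixed model needs more
#'   than one grouping level).
#' @param mass_mean_kg,mass_sd_kg Normal distribution of body mass.
#' @param sprint_mean_mps,sprint_sd_mps Normal distribution of the
#'   sprint-entry threshold, truncated above the 1.5 m/s walk boundary.
#' @param sigma_u SD of the athlete random intercept, arbitrary units.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with columns `athlete_id`, `mass_kg`,
#'   `sprint_entry_mps`, `random_intercept_au`.
#' @export
simulate_roster <- function(n_athletes = 19, mass_mean_kg = 69.7,
                            mass_sd_kg = 6.24, sprint_mean_mps = 5.2,
                            sprint_sd_mps = 0.3,
                            sigma_u = ground_truth_params()$sigma_u,
                            seed = NULL) {
  if (!is.numeric(n_athletes) || n_athletes < 2) {
    stop_invalid("n_athletes must be >= 2 (the mixed model needs > 1 group)")
  }
  check_number(mass_sd_kg, "mass_sd_kg", lower = 0)
  check_number(sigma_u, "sigma_u", lower = 0)
  with_seed(seed, {
    mass <- rnorm(n_athletes, mass_mean_kg, mass_sd_kg)
    spr <- rnorm(n_athletes, sprint_mean_mps, sprint_sd_mps)
    # truncate: redraw any threshold at or below the walk boundary
    while (any(bad <- spr <= 1.5)) {
      spr[bad] <- rnorm(sum(bad), sprint_mean_mps, sprint_sd_mps)
    }
    tibble(
      athlete_id = sprintf("A%02d", seq_len(n_athletes)),
      mass_kg = mass,
      sprint_entry_mps = spr,
      # exchangeable athlete effects, centred so they sum to zero in the
      # squad (the squad-mean load level belongs to the intercept)
      random_intercept_au = local({
        u <- rnorm(n_athletes, 0, sigma_u)
        if (sigma_u > 0) u - mean(u) else u
      })
    )
  })
}

#' Match configuration
#'
#' Sevens matches are two halves with a short halftime during which players
#' remain on the field; tournaments comprise five or six games.
#'
#' @param match_id,tournament_id Identifiers.
#' @param game_number Integer 1-6, the game's position in its tournament.
#' @param fielded_athletes Character vector of athlete ids fielded.
#' @param half_length_s,halftime_s Half and halftime lengths in seconds.
#' @param sample_rate_hz Sampling rate; GNSS units report at 10 Hz.
#' @return A list of class `match_config`.
#' @export
match_config <- function(match_id, tournament_id, game_number,
                         fielded_athletes, half_length_s = 420,
                         halftime_s = 120, sample_rate_hz = 10) {
  check_number(game_number, "game_number", lower = 1, upper = 6)
  if (sample_rate_hz != 10) stop_invalid("sample_rate_hz is fixed at 10")
  if (length(fielded_athletes) < 1) {
    stop_invalid("fielded_athletes must be non-empty")
  }
  structure(
    list(
      match_id = as.character(match_id),
      tournament_id = as.character(tournament_id),
      game_number = as.integer(game_number),
      fielded_athletes = as.character(fielded_athletes),
      half_length_s = half_length_s,
      halftime_s = halftime_s,
      sample_rate_hz = sample_rate_hz
    ),
    class = "match_config"
  )
}

#' Simulate one athlete-match 10 Hz speed trace
#'
#' Realises the semi-Markov movement model as a continuous piecewise-linear
#' speed signal sampled at 10 Hz over first half, halftime and second half.
#' The athlete either plays the full match or a contiguous substitution
#' window; off-field samples have speed 0. Halftime samples are flagged
#' `period = "HT"` with `on_field = TRUE` (players remain on the field) and
#' speed 0. Speed is tapered to zero at window and half boundaries at a
#' hard-ramp rate, so the signal never jumps faster than the hard-ramp
#' magnitude allows.
#'
#' @param profile One roster row (needs `athlete_id`, `sprint_entry_mps`).
#' @param match A [match_config()].
#' @param movement A [movement_profile()].
#' @param seed Integer seed.
#' @return A [speed_trace()].
#' @export
simulate_trace <- function(profile, match, movement = movement_profile(),
                           seed = NULL) {
  stopifnot(inherits(match, "match_config"))
  validate_movement_profile(movement)
  with_seed(seed, {
    hz <- match$sample_rate_hz
    h <- match$half_length_s
    ht <- match$halftime_s
    n <- as.integer((2 * h + ht) * hz)
    t_wall <- (seq_len(n) - 1L) / hz
    n1 <- as.integer(h * hz)
    nht <- as.integer(ht * hz)
    period <- rep(c("H1", "HT", "H2"), c(n1, nht, n - n1 - nht))
    is_play <- period != "HT"
    # play-time coordinate: seconds of match play elapsed at each sample
    t_play <- t_wall
    t_play[period == "HT"] <- NA_real_
    t_play[period == "H2"] <- t_wall[period == "H2"] - ht
    play_total <- 2 * h

    # substitution window in play-time coordinates
    if (runif(1) < movement$p_full_match) {
      w0 <- 0
      w1 <- play_total
    } else {
      len <- 60 * runif(1, movement$partial_range_min[1],
                        min(movement$partial_range_min[2], play_total / 60))
      w0 <- runif(1, 0, play_total - len)
      w1 <- w0 + len
    }
    on_field <- !is_play | (!is.na(t_play) & t_play >= w0 & t_play < w1)

    sprint_target <- profile$sprint_entry_mps + movement$speed_mean_mps["sprint"]
    bp <- simulate_state_chain(movement, duration_s = w1 - w0,
                               sprint_target = sprint_target)
    speed <- rep(0, n)
    idx <- which(on_field & is_play)
    speed[idx] <- approx(bp$t, bp$v, xout = t_play[idx] - w0,
                         rule = 2, ties = "ordered")$y

    # taper speed to zero toward every boundary where the athlete is (or
    # must be) stationary: window edges and the halftime ends of each half
    hard_max <- movement$ramp_hard_mps2[2]
    for (b in unique(c(w0, w1, h))) {
      gap <- abs(t_play[idx] - b)
      speed[idx] <- pmin(speed[idx], hard_max * gap)
    }
    speed[speed < 0] <- 0

    speed_trace(t_wall, speed, on_field, period,
                athlete_id = profile$athlete_id, match_id = match$match_id,
                sample_rate_hz = hz)
  })
}

# realise the semi-Markov chain as speed breakpoints (time, speed) over
# [0, duration_s]; linear interpolation between breakpoints is the signal
simulate_state_chain <- function(movement, duration_s, sprint_target) {
  if (duration_s <= 0) return(list(t = c(0, 1), v = c(0, 0)))
  tmat <- movement$transition
  dwell <- movement$mean_dwell_s
  mu <- movement$speed_mean_mps
  sd <- movement$speed_sd_mps
  n_guess <- max(16L, ceiling(duration_s / min(dwell)) + 8L)
  bt <- numeric(2L * n_guess + 4L)
  bv <- numeric(2L * n_guess + 4L)
  k <- 1L
  bt[1L] <- 0
  bv[1L] <- 0
  state <- 1L # stand
  t0 <- 0
  v0 <- 0
  while (t0 < duration_s) {
    d <- rexp(1L, 1 / dwell[state])
    target <- if (state == 4L) {
      max(0, sprint_target + rnorm(1L, 0, sd[state]))
    } else {
      max(0, rnorm(1L, mu[state], sd[state]))
    }
    going_up <- target > v0
    hard_p <- if (state == 5L) {
      1 # contact braking is always a hard deceleration
    } else if (max(v0, target) <= 1.7) {
      0 # shuffling between standing and walking never breaks 2 m/s^2
    } else if (state == 4L) {
      0.85 # reaching sprint speed demands a hard acceleration
    } else if (!going_up && v0 >= 4) {
      max(movement$hard_ramp_prob_down, 0.75) # pulling up from a sprint
    } else if (going_up) {
      movement$hard_ramp_prob_up
    } else {
      movement$hard_ramp_prob_down
    }
    rng <- if (runif(1L) < hard_p) movement$ramp_hard_mps2 else
      movement$ramp_mild_mps2
    rate <- runif(1L, rng[1], rng[2])
    ramp_dur <- abs(target - v0) / rate
    if (ramp_dur >= d) {
      v_end <- v0 + sign(target - v0) * rate * d
    } else {
      v_end <- target
      k <- k + 1L
      bt[k] <- t0 + ramp_dur
      bv[k] <- target
    }
    t0 <- t0 + d
    v0 <- v_end
    k <- k + 1L
    bt[k] <- t0
    bv[k] <- v_end
    if (k > length(bt) - 2L) {
      bt <- c(bt, numeric(length(bt)))
      bv <- c(bv, numeric(length(bv)))
    }
    state <- sample.int(5L, 1L, prob = tmat[state, ])
  }
  list(t = bt[seq_len(k)], v = bv[seq_len(k)])
}

#' Simulate a contact count for one player-match
#'
#' Contacts (tackles, carries, rucks) are video-coded counts in the real
#' workflow; here they are drawn from a negative binomial whose mean is
#' `rate_per_min` times on-field playing time. The default dispersion is
#' calibrated so that at the squad-mean playing time the count has mean 4
#' and SD 2.5 (overdispersed: a Poisson cannot have SD 2.5 at mean 4).
#'
#' @param trace A [speed_trace()]; playing time is taken from it.
#' @param rate_per_min Contact events per on-field minute (>= 0).
#' @param dispersion Negative-binomial size parameter; smaller = more
#'   overdispersed.
#' @param seed Integer seed.
#' @return A single non-negative integer count.
#' @export
simulate_contacts <- function(trace,
                              rate_per_min = movement_profile()$contact_rate_per_min,
                              dispersion = 7.111, seed = NULL) {
  if (!is.numeric(rate_per_min) || rate_per_min < 0) {
    stop_invalid("rate_per_min must be >= 0")
  }
  check_number(dispersion, "dispersion", lower = 0, allow_equal_lower = FALSE)
  minutes <- sum(play_mask(trace)) / (60 * trace_sample_rate(trace))
  mu <- rate_per_min * minutes
  if (mu == 0) return(0L)
  with_seed(seed, as.integer(rnbinom(1L, size = dispersion, mu = mu)))
}

#' Generating parameters of the synthetic study
#'
#' The ground truth behind the simulator's RPE responses: fixed-effect
#' coefficients on the standardised model design (with the fixed centring
#' and scaling constants used by the generator), the athlete-intercept and
#' residual SDs, additive game-number shifts (games 1-2 of a tournament
#' carry lower load), and the probability that an athlete fails to report
#' RPE. The sign pattern mirrors the fitted study: mass negative, contacts
#' and total distance positive, mild-deceleration main effect negative with
#' positive low/high-speed interactions, and all acceleration terms zero.
#'
#' @param beta Named coefficients (au per SD of predictor; `intercept` au).
#' @param scaling List with numeric `center` and `scale` per design column,
#'   fixed constants from the calibrated reference simulation.
#' @param sigma_u,sigma_e Athlete-intercept and residual SDs, au.
#' @param game_effect Named additive shifts (au) for game numbers 1-6.
#' @param rpe_missing_prob Probability an RPE report is missing, in [0, 1).
#' @return A list of class `ground_truth_params`.
#' @export
ground_truth_params <- function(
    beta = c(intercept = 98, mass_kg = -11, contacts = 12, total_m = 135,
             HA = 0, LD = -125, HD = 0, HA_LS = 0, HA_HS = 0,
             LD_LS = 8, LD_HS = 8, HD_LS = 0, HD_HS = 0),
    scaling = default_design_scaling(),
    sigma_u = 9, sigma_e = 20,
    game_effect = c(`1` = -34, `2` = -34, `3` = 17.8, `4` = 17.8,
                    `5` = 17.8, `6` = 17.8),
    duration_ref_min = 12.3,
    rpe_missing_prob = 186 / 1188) {
  check_number(sigma_u, "sigma_u", lower = 0)
  check_number(sigma_e, "sigma_e", lower = 0)
  if (rpe_missing_prob < 0 || rpe_missing_prob >= 1) {
    stop_invalid("rpe_missing_prob must be in [0, 1)")
  }
  need <- design_term_names()
  if (!all(c("intercept", need) %in% names(beta))) {
    stop_invalid(sprintf("beta must name: intercept, %s",
                         paste(need, collapse = ", ")))
  }
  check_number(duration_ref_min, "duration_ref_min", lower = 0,
               allow_equal_lower = FALSE)
  structure(
    list(beta = beta, scaling = scaling, sigma_u = sigma_u,
         sigma_e = sigma_e, game_effect = game_effect,
         duration_ref_min = duration_ref_min,
         rpe_missing_prob = rpe_missing_prob),
    class = "ground_truth_params"
  )
}

# non-intercept design columns of the workload model, in order
design_term_names <- function() {
  c("mass_kg", "contacts", "total_m", "HA", "LD", "HD",
    "HA_LS", "HA_HS", "LD_LS", "LD_HS", "HD_LS", "HD_HS")
}

# fixed centring/scaling constants for the generator's standardised design:
# means and SDs of the raw design columns in the calibrated reference
# simulation (squad of 19, 99 matches, 12 fielded, default movement profile)
default_design_scaling <- function() {
  list(
    center = c(mass_kg = 69.7, contacts = 4.2, total_m = 1117,
               HA = 23.5, LD = 1038, HD = 19.3,
               HA_LS = 1.72, HA_HS = 2.67, LD_LS = 278.7, LD_HS = 79.3,
               HD_LS = 2.50, HD_HS = 0.76),
    scale = c(mass_kg = 6.24, contacts = 2.65, total_m = 265.5,
              HA = 9.42, LD = 248.5, HD = 8.09,
              HA_LS = 0.66, HA_HS = 1.68, LD_LS = 75.6, LD_HS = 58.6,
              HD_LS = 0.90, HD_HS = 0.69)
  )
}

#' Simulate reported RPE for player-match records
#'
#' Draws the latent session load `sRPE* = X beta + (game shift + u_j) *
#' t / t_ref + eps * sqrt(t / t_ref)`, inverts it to a reported RPE by
#' dividing by playing time `t`, rounding to the integer 0-10 scale and
#' clamping, and censors the report completely at random with the
#' configured missingness probability. This inversion guarantees the
#' generated RPE is internally consistent with the sRPE later analysed.
#' The systematic game and athlete shifts scale linearly with playing time
#' (they are per-minute intensity effects), while the residual scales with
#' its square root (noise accumulating over exposure); all three have
#' exactly their nominal size at `duration_ref_min`. A substitute playing
#' a few minutes therefore cannot swing a whole match's worth of load.
#'
#' @param features Tibble with the raw design columns (see
#'   [design_term_names()]), `playing_time_min`, `game_number`, and
#'   `random_intercept_au` (the athlete's `u_j`).
#' @param truth A [ground_truth_params()].
#' @param seed Integer seed.
#' @param round Report on the integer 0-10 scale (default). With
#'   `round = FALSE` the exact latent quotient `sRPE*/t` is returned,
#'   unrounded and unclamped - the noise-free inversion used by
#'   parameter-recovery studies.
#' @return RPE vector (integer 0-10 when `round = TRUE`) with `NA` for
#'   missing reports.
#' @export
simulate_rpe <- function(features, truth = ground_truth_params(),
                         seed = NULL, round = TRUE) {
  stopifnot(inherits(truth, "ground_truth_params"))
  if (any(features$playing_time_min <= 0)) {
    stop_invalid("playing_time_min must be > 0 to invert sRPE to RPE")
  }
  need <- c(design_term_names(), "playing_time_min", "game_number",
            "random_intercept_au")
  if (!all(need %in% names(features))) {
    stop_invalid(sprintf("features must contain: %s",
                         paste(setdiff(need, names(features)),
                               collapse = ", ")))
  }
  with_seed(seed, {
    expo <- features$playing_time_min / truth$duration_ref_min
    # residual load noise accumulates over exposure like independent
    # increments: SD grows with the square root of playing time
    lat <- latent_srpe(features, truth) +
      sqrt(expo) * rnorm(nrow(features), 0, truth$sigma_e)
    rpe <- lat / features$playing_time_min
    if (round) rpe <- as.integer(pmin(10, pmax(0, round(rpe))))
    miss <- runif(nrow(features)) < truth$rpe_missing_prob
    rpe[miss] <- NA
    rpe
  })
}

# noise-free part of the latent session load: fixed effects plus the
# exposure-scaled game shift and athlete intercept
latent_srpe <- function(features, truth) {
  terms <- design_term_names()
  x <- as.matrix(features[terms])
  z <- sweep(sweep(x, 2, truth$scaling$center[terms]), 2,
             truth$scaling$scale[terms], "/")
  expo <- features$playing_time_min / truth$duration_ref_min
  drop(
    truth$beta[["intercept"]] + z %*% truth$beta[terms] +
      expo * (truth$game_effect[as.character(features$game_number)] +
                features$random_intercept_au)
  )
}

#' Study-level simulation configuration
#'
#' @param n_athletes Squad size (default 19).
#' @param n_matches Matches across all tournaments (default 99).
#' @param fielded_per_match Players fielded per match (default 12, the
#'   sevens tournament squad).
#' @param movement A [movement_profile()].
#' @param truth A [ground_truth_params()].
#' @param mass_mean_kg,mass_sd_kg,sprint_mean_mps,sprint_sd_mps Roster
#'   distribution parameters, passed to [simulate_roster()].
#' @param contact_dispersion Negative-binomial size for contact counts.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_athletes = 19, n_matches = 99,
                         fielded_per_match = 12,
                         movement = movement_profile(),
                         truth = ground_truth_params(),
                         mass_mean_kg = 69.7, mass_sd_kg = 6.24,
                         sprint_mean_mps = 5.2, sprint_sd_mps = 0.3,
                         contact_dispersion = 7.111) {
  if (fielded_per_match > n_athletes) {
    stop_invalid("fielded_per_match cannot exceed n_athletes")
  }
  check_number(n_matches, "n_matches", lower = 1)
  structure(
    list(n_athletes = n_athletes, n_matches = n_matches,
         fielded_per_match = fielded_per_match, movement = movement,
         truth = truth, mass_mean_kg = mass_mean_kg,
         mass_sd_kg = mass_sd_kg, sprint_mean_mps = sprint_mean_mps,
         sprint_sd_mps = sprint_sd_mps,
         contact_dispersion = contact_dispersion),
    class = "study_config"
  )
}

# split n_matches into tournaments of 6 and 5 games (sevens tournaments
# have five or six), preferring six-game tournaments so that game number 6
# is well represented; tiny n falls back to one short tournament
tournament_sizes <- function(n_matches) {
  b <- (6L - n_matches %% 6L) %% 6L # five-game tournaments
  a <- (n_matches - 5L * b) / 6L
  if (a < 0) {
    sizes <- rep(6L, n_matches %/% 6L)
    r <- n_matches %% 6L
    return(if (r > 0) c(sizes, r) else sizes)
  }
  c(rep(6L, a), rep(5L, b))
}

match_schedule <- function(n_matches) {
  sizes <- tournament_sizes(n_matches)
  tibble(
    match_id = sprintf("M%03d", seq_len(sum(sizes))),
    tournament_id = rep(sprintf("T%02d", seq_along(sizes)), sizes),
    game_number = unlist(lapply(sizes, seq_len), use.names = FALSE)
  )
}

#' Simulate a complete synthetic study
#'
#' Runs the full generative pipeline: roster, tournament schedule, one
#' 10 Hz speed trace per fielded player per match, zone kinematics on every
#' trace, contact counts, and RPE reports from the ground-truth workload
#' model — returning one player-match record per fielded player, including
#' records whose RPE report is missing (apply [drop_incomplete()] before
#' modelling).
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the entire dataset is reproducible from it.
#' @param keep_traces Keep the simulated traces (as a list attached as the
#'   `traces` attribute)? Default `FALSE`; a full study holds ~11 million
#'   samples.
#' @param exact_rpe Generate the exact latent RPE quotient instead of the
#'   rounded, clamped 0-10 report (see [simulate_rpe()]); used by
#'   recovery studies.
#' @return A `study_dataset` tibble with attributes `roster`, `schedule`,
#'   and `provenance` (config and seed).
#' @export
simulate_study <- function(config = study_config(), seed = 1,
                           keep_traces = FALSE, exact_rpe = FALSE) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_seeds(seed, 3L + config$n_matches)
  roster <- simulate_roster(
    config$n_athletes, config$mass_mean_kg, config$mass_sd_kg,
    config$sprint_mean_mps, config$sprint_sd_mps,
    sigma_u = config$truth$sigma_u, seed = seeds[1]
  )
  sched <- match_schedule(config$n_matches)
  n_rec <- nrow(sched) * config$fielded_per_match
  zone_rows <- vector("list", n_rec)
  contact_n <- integer(n_rec)
  rec_ath <- character(n_rec)
  rec_match <- character(n_rec)
  traces <- if (keep_traces) vector("list", n_rec) else NULL
  k <- 0L
  fielded_seeds <- derive_seeds(seeds[2], nrow(sched))
  for (m in seq_len(nrow(sched))) {
    fielded <- with_seed(
      fielded_seeds[m],
      sample(roster$athlete_id, config$fielded_per_match)
    )
    mc <- match_config(sched$match_id[m], sched$tournament_id[m],
                       sched$game_number[m], fielded)
    tr_seeds <- derive_seeds(seeds[3L + m], 2L * length(fielded))
    for (j in seq_along(fielded)) {
      k <- k + 1L
      prof <- roster[roster$athlete_id == fielded[j], ]
      tr <- simulate_trace(prof, mc, config$movement, seed = tr_seeds[j])
      acc <- compute_acceleration(tr)
      thr <- zone_thresholds(prof$sprint_entry_mps)
      zd <- accumulate_zone_distances(tr, acc, thr)
      zone_rows[[k]] <- c(zd$cells, total_m = zd$total_m,
                          playing_time_min = zd$playing_time_min)
      contact_n[k] <- simulate_contacts(
        tr, config$movement$contact_rate_per_min,
        config$contact_dispersion,
        seed = tr_seeds[length(fielded) + j]
      )
      rec_ath[k] <- fielded[j]
      rec_match[k] <- mc$match_id
      if (keep_traces) traces[[k]] <- tr
    }
  }
  zs <- as_tibble(do.call(rbind, zone_rows))
  zs$athlete_id <- rec_ath
  zs$match_id <- rec_match
  contacts <- tibble(athlete_id = rec_ath, match_id = rec_match,
                     contacts = contact_n)

  # assemble features for the RPE generator, then fuse everything
  feats <- zs |>
    dplyr::left_join(contacts, by = c("athlete_id", "match_id")) |>
    dplyr::left_join(roster, by = "athlete_id") |>
    dplyr::left_join(sched, by = "match_id")
  feats$HA <- feats$LS_HA + feats$MS_HA + feats$HS_HA
  feats$LD <- feats$LS_LD + feats$MS_LD + feats$HS_LD
  feats$HD <- feats$LS_HD + feats$MS_HD + feats$HS_HD
  feats$HA_LS <- feats$LS_HA; feats$HA_HS <- feats$HS_HA
  feats$LD_LS <- feats$LS_LD; feats$LD_HS <- feats$HS_LD
  feats$HD_LS <- feats$LS_HD; feats$HD_HS <- feats$HS_HD
  # mass enters the latent load relative to the squad mean: workload
  # contrasts are within-squad, and the squad-average level is the
  # intercept's job
  truth <- config$truth
  truth$scaling$center[["mass_kg"]] <- mean(roster$mass_kg)
  rpe <- simulate_rpe(feats, truth, seed = seeds[3], round = !exact_rpe)

  out <- build_records(
    zone_summaries = zs,
    contacts = contacts,
    roster = roster,
    rpe_reports = tibble(athlete_id = rec_ath, match_id = rec_match,
                         rpe_au = if (exact_rpe) NA_real_ else rpe),
    match_meta = sched
  )
  if (exact_rpe) {
    # exact latent quotients may fall outside the reportable 0-10 scale;
    # bypass the scale check that build_records applies to real reports
    out$rpe_au <- rpe
    out$srpe_au <- rpe * out$playing_time_min
  }
  attr(out, "roster") <- roster
  attr(out, "schedule") <- sched
  attr(out, "provenance") <- list(seed = seed, config = config)
  if (keep_traces) attr(out, "traces") <- traces
  out
}
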