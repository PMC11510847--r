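test_that("roster simulation honours its distributional contract", {
  r <- simulate_roster(19, 69.7, 6.24, seed = 1)
  expect_equal(nrow(r), 19)
  expect_false(anyDuplicated(r$athlete_id) > 0)
  # sample mean within 3 standard errors of the population mean
  expect_lt(abs(mean(r$mass_kg) - 69.7), 3 * 6.24 / sqrt(19))
  expect_true(all(r$sprint_entry_mps > 1.5))

  r0 <- simulate_roster(2, 70, 0, seed = 0)
  expect_equal(r0$mass_kg, c(70, 70))

  expect_identical(simulate_roster(19, 69.7, 6.24, seed = 1), r)
  expect_error(simulate_roster(1), class = "invalid_argument")
})

test_that("trace length and structure are fixed by the sampling contract", {
  r <- simulate_roster(seed = 3)
  mc <- match_config("M1", "T1", 1, r$athlete_id[1:12])
  tr <- simulate_trace(r[1, ], mc, seed = 11)
  expect_equal(nrow(tr), (2 * 420 + 120) * 10)
  expect_true(all(tr$speed_mps >= 0))
  expect_setequal(unique(tr$period), c("H1", "HT", "H2"))
  # halftime: on field but stationary
  expect_true(all(tr$on_field[tr$period == "HT"]))
  expect_true(all(tr$speed_mps[tr$period == "HT"] == 0))
  # substituted-off spans are stationary
  expect_true(all(tr$speed_mps[!tr$on_field] == 0))
})

test_that("a stand-only movement profile yields a silent trace", {
  mv <- movement_profile()
  mv$transition <- matrix(0, 5, 5)
  mv$transition[, 1] <- 1 # every state falls back to standing
  mv$speed_mean_mps[] <- 0
  mv$speed_sd_mps[] <- 0
  r <- simulate_roster(seed = 4)
  mc <- match_config("M1", "T1", 1, r$athlete_id[1])
  tr <- simulate_trace(r[1, ], mc, mv, seed = 2)
  expect_true(all(tr$speed_mps == 0))
})

test_that("traces are seed-reproducible and bounded in jump size", {
  r <- simulate_roster(seed = 5)
  mc <- match_config("M2", "T1", 2, r$athlete_id[1:3])
  t1 <- simulate_trace(r[2, ], mc, seed = 99)
  t2 <- simulate_trace(r[2, ], mc, seed = 99)
  expect_identical(t1$speed_mps, t2$speed_mps)
  t3 <- simulate_trace(r[2, ], mc, seed = 100)
  expect_false(identical(t1$speed_mps, t3$speed_mps))
  # no jump can exceed the hardest ramp over one sample interval
  hard_max <- movement_profile()$ramp_hard_mps2[2]
  expect_lte(max(abs(diff(t1$speed_mps))), hard_max * 0.1 + 1e-9)
})

test_that("simulated playing time matches the cohort profile", {
  r <- simulate_roster(seed = 6)
  mins <- replicate(400, {
    i <- sample.int(19, 1)
    mc <- match_config("MX", "TX", 1, r$athlete_id[i])
    tr <- simulate_trace(r[i, ], mc, seed = sample.int(1e7, 1))
    sum(tr$on_field & tr$period != "HT") / 600
  })
  expect_true(all(mins <= 14 + 1e-9))
  # cohort mean playing time: 11.8 min within 5%
  expect_lt(abs(mean(mins) - 11.8) / 11.8, 0.05)
})

test_that("contact counts are calibrated overdispersed negative binomials", {
  # trace with exactly the cohort-mean 11.8 minutes on field
  n_on <- 11.8 * 600
  per <- rep(c("H1", "HT", "H2"), c(4200, 1200, 4200))
  onf <- rep(FALSE, 9600)
  onf[which(per != "HT")[1:n_on]] <- TRUE
  tr <- speed_trace((0:9599) / 10, rep(0, 9600), onf, per)
  expect_equal(simulate_contacts(tr, rate_per_min = 0), 0L)
  expect_identical(simulate_contacts(tr, seed = 5),
                   simulate_contacts(tr, seed = 5))
  expect_error(simulate_contacts(tr, rate_per_min = -1),
               class = "invalid_argument")

  draws <- withr::with_seed(8, replicate(2000, simulate_contacts(tr)))
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - 4) / 4, 0.05)
  expect_lt(abs(sd(draws) - 2.5) / 2.5, 0.10)
})

test_that("RPE inversion is exact arithmetic when noise-free", {
  truth <- ground_truth_params(
    beta = c(intercept = 70, mass_kg = 0, contacts = 0, total_m = 0,
             HA = 0, LD = 0, HD = 0, HA_LS = 0, HA_HS = 0,
             LD_LS = 0, LD_HS = 0, HD_LS = 0, HD_HS = 0),
    sigma_u = 0, sigma_e = 0,
    game_effect = c(`1` = 0, `2` = 0, `3` = 0, `4` = 0, `5` = 0, `6` = 0),
    rpe_missing_prob = 0
  )
  ctr <- truth$scaling$center
  feats <- tibble::as_tibble(as.list(ctr)) # all predictors at their centres
  feats$playing_time_min <- 10
  feats$game_number <- 3
  feats$random_intercept_au <- 0
  expect_identical(simulate_rpe(feats, truth, seed = 1), 7L)

  truth$rpe_missing_prob <- 1 - 1e-12
  expect_true(is.na(simulate_rpe(feats, truth, seed = 1)))

  feats$playing_time_min <- 0
  expect_error(simulate_rpe(feats, truth), class = "invalid_argument")
})

test_that("reported RPE stays on the integer 0-10 scale", {
  ds <- small_study()
  rpe <- ds$rpe_au[!is.na(ds$rpe_au)]
  expect_true(all(rpe %in% 0:10))
  expect_equal(ds$srpe_au[!is.na(ds$rpe_au)],
               rpe * ds$playing_time_min[!is.na(ds$rpe_au)])
})

test_that("study assembly is structural: rows, keys, reproducibility", {
  cfg <- study_config(n_matches = 1, n_athletes = 5, fielded_per_match = 2)
  ds <- simulate_study(cfg, seed = 3)
  expect_equal(nrow(ds), 2)

  cfg2 <- study_config(n_matches = 3, n_athletes = 6, fielded_per_match = 4)
  d1 <- simulate_study(cfg2, seed = 9)
  d2 <- simulate_study(cfg2, seed = 9)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
  expect_false(anyDuplicated(paste(d1$athlete_id, d1$match_id)) > 0)
  expect_true(all(d1$playing_time_min <= 14 + 1e-9))
  expect_true(all(d1$game_number %in% 1:6))

  ds <- small_study()
  expect_equal(nrow(ds), 12 * 12)
  # every record's cells sum to its total
  expect_equal(rowSums(as.matrix(ds[zone_cell_names()])), ds$total_m,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("tournament schedules use five- and six-game tournaments", {
  expect_equal(sum(sevensload:::tournament_sizes(99)), 99)
  expect_true(all(sevensload:::tournament_sizes(99) %in% 5:6))
  expect_equal(sum(sevensload:::tournament_sizes(30)), 30)
  sched <- sevensload:::match_schedule(99)
  expect_equal(nrow(sched), 99)
  expect_true(all(table(sched$game_number)[as.character(1:5)] > 0))
})
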