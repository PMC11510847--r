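# balanced long table built directly: athletes x games x types, with
# controllable game means and per-type offsets
synthetic_long <- function(n_athletes = 6, games = 1:6, reps = 4,
                           game_means = rep(100, 6), type_shift = 0,
                           noise_sd = 5, seed = 1) {
  withr::with_seed(seed, {
    rows <- expand.grid(
      athlete_id = sprintf("A%02d", seq_len(n_athletes)),
      game_number = games,
      rep = seq_len(reps),
      stringsAsFactors = FALSE
    )
    rows$match_id <- sprintf("M_%d_%d", rows$game_number, rows$rep)
    base <- game_means[rows$game_number] +
      rnorm(nrow(rows), 0, noise_sd)
    long <- dplyr::bind_rows(
      dplyr::mutate(rows, srpe_type = "actual", srpe_au = base),
      dplyr::mutate(rows, srpe_type = "predicted",
                    srpe_au = base + type_shift)
    )
    long$match_id <- paste(long$athlete_id, long$match_id)
    structure(long[c("athlete_id", "match_id", "game_number", "srpe_type",
                     "srpe_au")],
              class = c("long_eval_table", class(long)))
  })
}

test_that("the long table doubles each record into actual and predicted", {
  ds <- small_complete()
  fit <- small_fit()
  long <- make_long_table(ds, fit)
  expect_equal(nrow(long), 2 * nrow(ds))
  expect_equal(sort(unique(long$srpe_type)), c("actual", "predicted"))
  counts <- table(paste(long$athlete_id, long$match_id))
  expect_true(all(counts == 2))
})

test_that("zero-noise predictions coincide with observations row by row", {
  zn <- zero_noise_study()
  long <- make_long_table(zn$dataset, zn$fit)
  wide <- tidyr::pivot_wider(tibble::as_tibble(long),
                             names_from = "srpe_type",
                             values_from = "srpe_au")
  expect_equal(wide$actual, wide$predicted, tolerance = 1e-6)
  an <- rm_anova(long)
  expect_lt(an$f[an$term == "srpe_type"], 1e-6)
  expect_gt(an$p[an$term == "srpe_type"], 0.999)
})

test_that("identical cell values give an all-zero ANOVA", {
  long <- synthetic_long(noise_sd = 0, game_means = rep(50, 6))
  an <- rm_anova(long)
  expect_equal(an$f[an$term != "residual"], rep(0, 3))
  expect_equal(an$p[an$term != "residual"], rep(1, 3))
})

test_that("the ANOVA decomposes sums of squares on balanced designs", {
  long <- synthetic_long(game_means = c(80, 85, 100, 100, 110, 120),
                         type_shift = 3, noise_sd = 8, seed = 4)
  an <- rm_anova(long)
  athlete_ss <- as.data.frame(attr(an, "athlete_stratum")[[1]])[["Sum Sq"]]
  total_ss <- sum((long$srpe_au - mean(long$srpe_au))^2)
  expect_equal(sum(an$ss) + sum(athlete_ss), total_ss, tolerance = 1e-6)
  expect_equal(an$df[an$term == "game_number"], 5)
  expect_equal(an$df[an$term == "srpe_type"], 1)
  expect_equal(an$df[an$term == "game_number:srpe_type"], 5)
})

test_that("single-game tables are refused", {
  long <- synthetic_long(games = 1)
  expect_error(rm_anova(long), class = "invalid_argument",
               regexp = "game numbers")
})

test_that("Tukey flags exactly the separated games and matches brute force", {
  # games 1-2 sit far below games 3-6
  long <- synthetic_long(game_means = c(60, 60, 100, 100, 100, 100),
                         noise_sd = 6, reps = 8, seed = 5)
  tk <- tukey_game(long)
  sep <- with(tk, significant)
  pairs <- tk$comparison
  low_high <- grepl("^[3-6]-[12]$|^[12]-[3-6]$", pairs)
  expect_true(all(tk$significant[low_high]))
  expect_false(any(tk$significant[!low_high]))

  # brute-force studentized-range agreement on a three-group table
  long3 <- synthetic_long(games = 1:3, game_means = c(80, 95, 110, 0, 0, 0),
                          noise_sd = 10, reps = 6, seed = 6)
  tk3 <- tukey_game(long3)
  d <- data.frame(
    athlete = factor(long3$athlete_id), game = factor(long3$game_number),
    type = factor(long3$srpe_type), y = long3$srpe_au
  )
  fit <- stats::aov(y ~ athlete + type + game, data = d)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(d$y, d$game, mean)
  n_g <- tapply(d$y, d$game, length)
  for (cmp in tk3$comparison) {
    gs <- strsplit(cmp, "-")[[1]]
    diff_means <- means[[gs[1]]] - means[[gs[2]]]
    se <- sqrt(mse / 2 * (1 / n_g[[gs[1]]] + 1 / n_g[[gs[2]]]))
    p_ref <- stats::ptukey(abs(diff_means) / se, nmeans = 3,
                           df = stats::df.residual(fit),
                           lower.tail = FALSE)
    row <- tk3[tk3$comparison == cmp, ]
    expect_equal(row$diff, unname(diff_means), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(row$p_adj, unname(p_ref), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("equal game means produce no post hoc flags", {
  zn <- zero_noise_study()
  long <- make_long_table(zn$dataset, zn$fit)
  tk <- tukey_game(long)
  # noise-free generator with zero game effect: nothing to find
  expect_false(any(tk$significant))
})

test_that("paired type comparisons localise an injected bias", {
  long <- synthetic_long(noise_sd = 6, seed = 8, reps = 6)
  bump <- long$srpe_type == "predicted" & long$game_number %in% 1:2
  long$srpe_au[bump] <- long$srpe_au[bump] + 20
  pw <- pairwise_type_by_game(long)
  expect_equal(pw$game_number[pw$significant], 1:2)
  expect_true(all(abs(pw$mean_diff[1:2] + 20) < 3))

  # order invariance: shuffling rows changes nothing
  shuffled <- long[withr::with_seed(9, sample(nrow(long))), ]
  pw2 <- pairwise_type_by_game(shuffled)
  expect_equal(pw2, pw)

  # Holm adjustment never decreases a p value
  expect_true(all(pw$p_adj >= pw$p - 1e-15))
})

test_that("identical types give p = 1 everywhere; orphans are refused", {
  long <- synthetic_long(type_shift = 0, noise_sd = 0)
  pw <- pairwise_type_by_game(long)
  expect_equal(pw$p_adj, rep(1, 6))
  expect_false(any(pw$significant))

  broken <- synthetic_long()[-1, ]
  expect_error(pairwise_type_by_game(broken), class = "pairing_error")
  expect_error(rm_anova(broken), class = "invalid_argument")
})
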