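#' Long actual-vs-predicted sRPE table
#'
#' Stacks each complete player-match record into two evaluation rows: the
#' observed sRPE and the model-predicted sRPE, keyed by athlete, match and
#' game number.
#'
#' @param dataset Complete `study_dataset` the model was fitted to.
#' @param fit A `workload_fit` from [fit_workload_model()].
#' @param include_random Use BLUPs in the predictions (default `TRUE`).
#' @return Tibble of class `long_eval_table` with columns `athlete_id`,
#'   `match_id`, `game_number`, `srpe_type` (`actual`/`predicted`),
#'   `srpe_au`.
#' @export
make_long_table <- function(dataset, fit, include_random = TRUE) {
  pred <- predict_srpe(fit, dataset, include_random = include_random)
  base <- dataset[c("athlete_id", "match_id", "game_number")]
  out <- dplyr::bind_rows(
    dplyr::mutate(base, srpe_type = "actual", srpe_au = dataset$srpe_au),
    dplyr::mutate(base, srpe_type = "predicted", srpe_au = pred)
  )
  class(out) <- unique(c("long_eval_table", class(out)))
  out
}

validate_long_table <- function(table) {
  need <- c("athlete_id", "match_id", "game_number", "srpe_type", "srpe_au")
  if (!all(need %in% names(table))) {
    stop_invalid(sprintf("long table must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  counts <- table(paste(table$athlete_id, table$match_id))
  if (any(counts != 2)) {
    stop_invalid("each (athlete, match) must contribute exactly two rows")
  }
  invisible(table)
}

#' Repeated-measures ANOVA of sRPE by game number and type
#'
#' Two-factor ANOVA (game number x sRPE type, with interaction) with the
#' athlete as the repeated unit, implemented by removing the athlete as a
#' blocking factor into an error stratum. Terms with (numerically) zero
#' sum-of-squares are reported with `F = 0`, `p = 1` rather than
#' undefined.
#'
#' @param table A `long_eval_table` from [make_long_table()].
#' @return Tibble of class `anova_table`: one row per term
#'   (`game_number`, `srpe_type`, `game_number:srpe_type`, `residual`)
#'   with `df`, `ss`, `f`, `p`.
#' @export
rm_anova <- function(table) {
  validate_long_table(table)
  games <- table(table$game_number)
  if (length(games) < 2) stop_invalid("need >= 2 game numbers")
  if (any(games < 2)) {
    abort(sprintf("game numbers with < 2 observations: %s",
                  paste(names(games)[games < 2], collapse = ", ")),
          class = c("degenerate_design", "sevensload_error"))
  }
  d <- data.frame(
    athlete = factor(table$athlete_id),
    game = factor(table$game_number),
    type = factor(table$srpe_type),
    y = table$srpe_au
  )
  fit <- stats::aov(y ~ game * type + Error(athlete), data = d)
  s <- summary(fit)
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- trimws(rownames(within))
  pick <- function(term) {
    i <- match(term, rn)
    within[i, ]
  }
  res <- pick("Residuals")
  term_map <- c(game_number = "game", srpe_type = "type",
                `game_number:srpe_type` = "game:type")
  rows <- lapply(names(term_map), function(nm) {
    r <- pick(term_map[[nm]])
    f <- r[["F value"]]
    p <- r[["Pr(>F)"]]
    if (!is.finite(f) || r[["Sum Sq"]] < 1e-12) {
      f <- 0
      p <- 1
    }
    tibble(term = nm, df = r[["Df"]], ss = r[["Sum Sq"]], f = f, p = p)
  })
  out <- dplyr::bind_rows(
    rows,
    tibble(term = "residual", df = res[["Df"]], ss = res[["Sum Sq"]],
           f = NA_real_, p = NA_real_)
  )
  attr(out, "athlete_stratum") <- s[["Error: athlete"]]
  class(out) <- unique(c("anova_table", class(out)))
  out
}

#' Tukey HSD post hoc on game number
#'
#' All 15 pairwise comparisons of the game-number marginal means (both sRPE
#' types pooled), Tukey-adjusted, athlete and type controlled as additive
#' blocks; significance flagged at `alpha`.
#'
#' @param table A `long_eval_table`.
#' @param alpha Familywise significance level (default 0.01).
#' @return Tibble of class `posthoc_result`: `comparison` (e.g. `"3-1"`),
#'   `diff` (mean difference, au), `p_adj`, `significant`.
#' @export
tukey_game <- function(table, alpha = 0.01) {
  validate_long_table(table)
  d <- data.frame(
    athlete = factor(table$athlete_id),
    game = factor(table$game_number),
    type = factor(table$srpe_type),
    y = table$srpe_au
  )
  fit <- stats::aov(y ~ athlete + type + game, data = d)
  tk <- stats::TukeyHSD(fit, which = "game")$game
  out <- tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("posthoc_result", class(out)))
  out
}

#' Paired actual-vs-predicted comparison within each game number
#'
#' For each game number, a paired t test of actual versus predicted sRPE
#' (paired on the player-match), with Holm adjustment across the games.
#' Degenerate games where every paired difference is identical are reported
#' with `p = 1` when the common difference is zero and `p = 0` otherwise.
#'
#' @param table A `long_eval_table`.
#' @param alpha Significance level after adjustment (default 0.01).
#' @return Tibble of class `posthoc_result`: `game_number`, `n_pairs`,
#'   `mean_diff` (actual minus predicted, au), `p`, `p_adj`, `significant`.
#' @export
pairwise_type_by_game <- function(table, alpha = 0.01) {
  key <- paste(table$athlete_id, table$match_id, sep = "/")
  counts <- table(key)
  if (any(counts != 2)) {
    abort(sprintf("unpaired rows for: %s",
                  paste(names(counts)[counts != 2], collapse = ", ")),
          class = c("pairing_error", "sevensload_error"))
  }
  wide <- tidyr::pivot_wider(
    as_tibble(table),
    id_cols = c("athlete_id", "match_id", "game_number"),
    names_from = "srpe_type", values_from = "srpe_au"
  )
  if (anyNA(wide$actual) || anyNA(wide$predicted)) {
    orphans <- wide[is.na(wide$actual) | is.na(wide$predicted), ]
    abort(sprintf("unpaired rows for: %s",
                  paste(paste(orphans$athlete_id, orphans$match_id, sep = "/"),
                        collapse = ", ")),
          class = c("pairing_error", "sevensload_error"))
  }
  games <- sort(unique(wide$game_number))
  rows <- lapply(games, function(g) {
    w <- wide[wide$game_number == g, ]
    diffs <- w$actual - w$predicted
    degenerate <- length(diffs) < 2 ||
      stats::sd(diffs) <= 1e-10 * max(1, abs(mean(diffs)))
    if (degenerate) {
      p <- if (isTRUE(all.equal(mean(diffs), 0))) 1 else 0
    } else {
      p <- stats::t.test(w$actual, w$predicted, paired = TRUE)$p.value
    }
    tibble(game_number = g, n_pairs = nrow(w), mean_diff = mean(diffs), p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("posthoc_result", class(out)))
  out
}
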