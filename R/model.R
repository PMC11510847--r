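#' Workload model specification
#'
#' Fixes the term structure of the mixed-effects workload model: sRPE
#' regressed on athlete mass, contact count, total distance, the three
#' non-reference acceleration-type distance sums (`HA`, `LD`, `HD`; mild
#' acceleration `LA` is the reference and its contribution lives in total
#' distance), and the six acceleration-by-speed interaction distances for
#' the low- and high-speed zones (moderate speed is the reference), with a
#' random intercept per athlete. Total distance is the sum of all twelve
#' cells, so including the `LA` sum as well would be exactly collinear.
#'
#' @param standardize Z-score all non-intercept predictors (default `TRUE`;
#'   zone distances span two orders of magnitude, so this conditions the
#'   optimiser). t statistics are invariant to this choice.
#' @param reml Fit by REML (default) rather than ML.
#' @param scaling Optional fixed `list(center, scale)` named per design
#'   column, overriding sample standardisation (used e.g. to fit on the
#'   generator's own scale in recovery studies).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(standardize = TRUE, reml = TRUE, scaling = NULL) {
  structure(list(standardize = standardize, reml = reml, scaling = scaling),
            class = "model_spec")
}

#' Build the fixed-effects design for the workload model
#'
#' Assembles the 13-column fixed design (intercept plus the 12 terms of
#' [design_term_names()]) from a complete record set, optionally
#' standardised, plus the athlete grouping vector.
#'
#' @param dataset Complete `study_dataset` (after [drop_incomplete()]).
#' @param spec A [model_spec()].
#' @param check_rank Raise a collinearity error when the design is rank
#'   deficient (default; prediction-time designs skip the check).
#' @return List with `X` (n x 13 matrix), `grouping` (athlete ids),
#'   `center`/`scale` actually applied, and `terms`.
#' @export
build_design <- function(dataset, spec = model_spec(), check_rank = TRUE) {
  terms <- design_term_names()
  d <- dataset
  d$HA <- d$LS_HA + d$MS_HA + d$HS_HA
  d$LD <- d$LS_LD + d$MS_LD + d$HS_LD
  d$HD <- d$LS_HD + d$MS_HD + d$HS_HD
  d$HA_LS <- d$LS_HA; d$HA_HS <- d$HS_HA
  d$LD_LS <- d$LS_LD; d$LD_HS <- d$HS_LD
  d$HD_LS <- d$LS_HD; d$HD_HS <- d$HS_HD
  x <- as.matrix(d[terms])
  if (anyNA(x)) stop_invalid("design variables contain missing values")
  if (isTRUE(spec$standardize)) {
    if (!is.null(spec$scaling)) {
      ctr <- spec$scaling$center[terms]
      scl <- spec$scaling$scale[terms]
    } else {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
    }
  } else {
    ctr <- setNames(rep(0, length(terms)), terms)
    scl <- setNames(rep(1, length(terms)), terms)
  }
  if (any(scl == 0 | !is.finite(scl))) {
    bad <- terms[scl == 0 | !is.finite(scl)]
    abort(
      sprintf("design columns with zero variance: %s",
              paste(bad, collapse = ", ")),
      class = c("collinearity_error", "sevensload_error")
    )
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  X <- cbind(`(Intercept)` = 1, z)
  qrx <- if (check_rank) qr(X) else NULL
  if (check_rank && qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(
      sprintf("design is rank deficient; offending columns: %s",
              paste(bad, collapse = ", ")),
      class = c("collinearity_error", "sevensload_error")
    )
  }
  list(X = X, grouping = as.character(dataset$athlete_id),
       center = ctr, scale = scl, terms = terms)
}

#' Fit the mixed-effects workload model
#'
#' REML-fitted random-intercept linear mixed model of sRPE on the design of
#' [build_design()], with per-term Wald t tests on Satterthwaite degrees of
#' freedom. A singular random-effect variance is reported as
#' `sigma_u_hat = 0` with a warning rather than an error.
#'
#' @param dataset Complete `study_dataset` (>= 2 athletes; more
#'   observations than fixed terms).
#' @param spec A [model_spec()].
#' @return An object of class `workload_fit`: `coefficients` (tibble with
#'   estimate, SE, df, t, p per term), `sigma_u_hat`, `sigma_e_hat`,
#'   `blups` (named per athlete), `r2_adjusted` (conditional) and
#'   `r2_adjusted_marginal`, `n_obs`, `n_athletes`, `converged`, plus the
#'   underlying `lmerMod` in `$model`.
#' @export
fit_workload_model <- function(dataset, spec = model_spec()) {
  des <- build_design(dataset, spec)
  n_ath <- length(unique(des$grouping))
  if (n_ath < 2) stop_invalid("need >= 2 athletes to fit a mixed model")
  if (nrow(des$X) <= ncol(des$X)) {
    stop_invalid("need more observations than fixed-effect terms")
  }
  dat <- as.data.frame(des$X[, -1, drop = FALSE])
  dat$srpe_au <- dataset$srpe_au
  dat$athlete_id <- des$grouping
  form <- stats::as.formula(paste(
    "srpe_au ~", paste(des$terms, collapse = " + "), "+ (1 | athlete_id)"
  ))
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = dat, REML = spec$reml),
    message = function(m) invokeRestart("muffleMessage")
  )
  if (lme4::isSingular(fit)) {
    warn("random-effect variance is singular; sigma_u_hat reported as 0")
  }
  conv <- length(fit@optinfo$conv$lme4) == 0 &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
  smry <- suppressMessages(summary(fit))
  co <- smry$coefficients
  coefs <- tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    df = unname(co[, "df"]),
    t = unname(co[, "t value"]),
    p = unname(co[, "Pr(>|t|)"])
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "athlete_id"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  re <- lme4::ranef(fit)$athlete_id
  blups <- setNames(re[["(Intercept)"]], rownames(re))
  out <- structure(
    list(
      model = fit,
      coefficients = coefs,
      sigma_u_hat = sigma_u,
      sigma_e_hat = sigma_e,
      blups = blups,
      n_obs = nrow(dat),
      n_athletes = n_ath,
      converged = conv,
      spec = spec,
      center = des$center,
      scale = des$scale,
      terms = des$terms
    ),
    class = "workload_fit"
  )
  r2 <- adjusted_r2(out, dataset)
  out$r2 <- r2
  out$r2_adjusted <- r2$conditional_adjusted
  out$r2_adjusted_marginal <- r2$marginal_adjusted
  out
}

#' @export
print.workload_fit <- function(x, ...) {
  cat(sprintf(
    "<workload_fit> %d records, %d athletes; sigma_u = %.2f, sigma_e = %.2f\n",
    x$n_obs, x$n_athletes, x$sigma_u_hat, x$sigma_e_hat
  ))
  cat(sprintf(
    "adjusted R2: %.3f (conditional), %.3f (marginal); converged: %s\n",
    x$r2_adjusted, x$r2_adjusted_marginal, x$converged
  ))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Adjusted R-squared of a workload fit
#'
#' R^2 is the squared correlation between observed sRPE and fitted values;
#' the conditional variant uses fixed effects plus athlete BLUPs, the
#' marginal variant fixed effects only. Both are adjusted as
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p = 12` non-intercept fixed
#' terms.
#'
#' @param fit A `workload_fit`.
#' @param dataset The records the model was fitted to.
#' @return List with `conditional`, `conditional_adjusted`, `marginal`,
#'   `marginal_adjusted`.
#' @export
adjusted_r2 <- function(fit, dataset) {
  stopifnot(inherits(fit, "workload_fit"))
  obs <- dataset$srpe_au
  n <- length(obs)
  p <- length(fit$terms)
  if (n <= p + 1) stop_invalid("need n > p + 1 observations to adjust R2")
  cond <- stats::fitted(fit$model)
  marg <- predict_srpe(fit, dataset, include_random = FALSE)
  r2_of <- function(pred) {
    if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
      # degenerate (e.g. perfect constant fit): fall back on residual SS
      1 - sum((obs - pred)^2) / max(sum((obs - mean(obs))^2),
                                    .Machine$double.eps)
    } else {
      stats::cor(obs, pred)^2
    }
  }
  adj <- function(r2) 1 - (1 - r2) * (n - 1) / (n - p - 1)
  r2c <- r2_of(cond)
  r2m <- r2_of(marg)
  list(
    conditional = r2c, conditional_adjusted = adj(r2c),
    marginal = r2m, marginal_adjusted = adj(r2m)
  )
}

#' Predict sRPE for player-match records
#'
#' Applies the fitted fixed effects (on the scaling used at fit time),
#' optionally adding the athlete's BLUP. Athletes unseen at fit time get a
#' random part of 0, with a warning.
#'
#' @param fit A `workload_fit`.
#' @param records Records carrying all predictor columns.
#' @param include_random Add athlete BLUPs (default `TRUE`).
#' @return Numeric vector of predicted sRPE, au.
#' @export
predict_srpe <- function(fit, records, include_random = TRUE) {
  stopifnot(inherits(fit, "workload_fit"))
  des <- build_design(
    records,
    model_spec(standardize = TRUE, reml = fit$spec$reml,
               scaling = list(center = fit$center, scale = fit$scale)),
    check_rank = FALSE
  )
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  pred <- drop(des$X %*% beta[colnames(des$X)])
  if (include_random) {
    u <- fit$blups[des$grouping]
    if (anyNA(u)) {
      warn("athletes unseen at fit time: random part taken as 0")
      u[is.na(u)] <- 0
    }
    pred <- pred + unname(u)
  }
  pred
}
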