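#' Run configuration for the end-to-end pipeline
#'
#' One object (serialisable as YAML) tying together the seed, output paths
#' and per-stage settings. Defaults reproduce the calibrated study profile.
#'
#' @param seed Master seed for all randomness.
#' @param out_dir Directory for all stage outputs.
#' @param config A [study_config()].
#' @param spec A [model_spec()].
#' @param alpha Evaluation significance level.
#' @param write_traces Also write every simulated trace as CSV (slow and
#'   large; default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = "sevensload_run",
                       config = study_config(), spec = model_spec(),
                       alpha = 0.01, write_traces = FALSE) {
  structure(
    list(seed = seed, out_dir = out_dir, config = config, spec = spec,
         alpha = alpha, write_traces = write_traces),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' Only scalar overrides of the defaults are serialised: seed, paths,
#' study sizes (`n_athletes`, `n_matches`, `fielded_per_match`), roster
#' moments, `alpha`, and the model flags.
#'
#' @param path YAML file path.
#' @param rc A [run_config()].
#' @name run-config-io
NULL

#' @rdname run-config-io
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) {
    abort("run config must name a seed",
          class = c("config_error", "sevensload_error"))
  }
  sc <- do.call(study_config, y$study %||% list())
  ms <- do.call(model_spec, y$model %||% list())
  run_config(
    seed = y$seed,
    out_dir = y$out_dir %||% "sevensload_run",
    config = sc, spec = ms,
    alpha = y$alpha %||% 0.01,
    write_traces = isTRUE(y$write_traces)
  )
}

#' @rdname run-config-io
#' @export
write_run_config <- function(rc, path) {
  y <- list(
    seed = rc$seed, out_dir = rc$out_dir, alpha = rc$alpha,
    write_traces = rc$write_traces,
    study = list(
      n_athletes = rc$config$n_athletes, n_matches = rc$config$n_matches,
      fielded_per_match = rc$config$fielded_per_match,
      mass_mean_kg = rc$config$mass_mean_kg,
      mass_sd_kg = rc$config$mass_sd_kg,
      sprint_mean_mps = rc$config$sprint_mean_mps,
      sprint_sd_mps = rc$config$sprint_sd_mps,
      contact_dispersion = rc$config$contact_dispersion
    ),
    model = list(standardize = rc$spec$standardize, reml = rc$spec$reml)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Pipeline stages
#'
#' The four analysis stages plus an orchestrator, each deterministic given
#' the configured seed. `run_simulate` generates the study and writes the
#' roster and records CSVs; `run_extract` re-derives zone distances from
#' written traces when present (and otherwise validates the simulated
#' summaries); `run_fit` fits the workload model and writes the JSON/CSV
#' fit report; `run_evaluate` writes the ANOVA, post hoc and pairwise
#' tables; `run_reproduce` chains all four and writes a study summary
#' (descriptive means, complete-record count, zone profile, adjusted
#' R-squared) plus a machine-readable manifest.
#'
#' @param rc A [run_config()].
#' @param dataset,fit Intermediate artifacts, passed between stages.
#' @return Each stage returns its main artifact invisibly-ish; see details.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(rc) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_study(rc$config, seed = rc$seed,
                       keep_traces = isTRUE(rc$write_traces))
  roster <- attr(ds, "roster")
  write_roster_csv(roster, file.path(rc$out_dir, "roster.csv"))
  write_records_csv(ds, file.path(rc$out_dir, "records.csv"))
  if (isTRUE(rc$write_traces)) {
    tdir <- file.path(rc$out_dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (tr in attr(ds, "traces")) {
      write_trace_csv(tr, file.path(tdir, sprintf(
        "%s_%s.csv", attr(tr, "match_id"), attr(tr, "athlete_id")
      )))
    }
  }
  stage_log("simulate", "%d records (%d athletes, %d matches) -> %s",
            nrow(ds), nrow(roster), rc$config$n_matches, rc$out_dir)
  ds
}

#' @rdname pipeline
#' @export
run_extract <- function(rc, dataset = NULL) {
  tdir <- file.path(rc$out_dir, "traces")
  if (is.null(dataset)) {
    rec_path <- file.path(rc$out_dir, "records.csv")
    if (!file.exists(rec_path)) {
      abort(sprintf("no records at %s; run run_simulate first", rec_path),
            class = c("data_error", "sevensload_error"))
    }
    dataset <- read_records_csv(rec_path)
  }
  if (dir.exists(tdir)) {
    roster <- read_roster_csv(file.path(rc$out_dir, "roster.csv"))
    files <- list.files(tdir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) {
      abort(sprintf("trace directory %s is empty", tdir),
            class = c("data_error", "sevensload_error"))
    }
    rows <- lapply(files, function(f) {
      ids <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
      tr <- read_trace_csv(f, athlete_id = ids[2], match_id = ids[1])
      prof <- roster[roster$athlete_id == ids[2], ]
      zd <- accumulate_zone_distances(
        tr, compute_acceleration(tr),
        zone_thresholds(prof$sprint_entry_mps)
      )
      c(zd$cells, total_m = zd$total_m,
        playing_time_min = zd$playing_time_min)
    })
    zs <- as_tibble(do.call(rbind, rows))
    stage_log("extract", "re-derived zone distances for %d traces",
              length(files))
    zs$athlete_id <- vapply(files, function(f)
      strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]][2], character(1))
    zs$match_id <- vapply(files, function(f)
      strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]][1], character(1))
    utils::write.csv(as.data.frame(zs),
                     file.path(rc$out_dir, "zone_distances.csv"),
                     row.names = FALSE)
  } else {
    utils::write.csv(
      as.data.frame(dataset[c("athlete_id", "match_id", zone_cell_names(),
                              "total_m", "playing_time_min")]),
      file.path(rc$out_dir, "zone_distances.csv"), row.names = FALSE
    )
    stage_log("extract", "wrote zone distances for %d records", nrow(dataset))
  }
  dataset
}

#' @rdname pipeline
#' @export
run_fit <- function(rc, dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- read_records_csv(file.path(rc$out_dir, "records.csv"))
  }
  complete <- drop_incomplete(dataset, quiet = TRUE)
  fit <- fit_workload_model(complete, rc$spec)
  write_fit_report(fit, file.path(rc$out_dir, "fit_report.json"),
                   file.path(rc$out_dir, "coefficients.csv"))
  stage_log("fit", "%d complete records, adjusted R2 = %.3f",
            fit$n_obs, fit$r2_adjusted)
  list(fit = fit, complete = complete)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(rc, dataset, fit) {
  long <- make_long_table(dataset, fit)
  an <- rm_anova(long)
  tk <- tukey_game(long, alpha = rc$alpha)
  pw <- pairwise_type_by_game(long, alpha = rc$alpha)
  utils::write.csv(as.data.frame(an),
                   file.path(rc$out_dir, "anova.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tk),
                   file.path(rc$out_dir, "tukey_game.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pw),
                   file.path(rc$out_dir, "pairwise_type_by_game.csv"),
                   row.names = FALSE)
  stage_log("evaluate", "game p = %.3g, type p = %.3g",
            an$p[an$term == "game_number"], an$p[an$term == "srpe_type"])
  list(anova = an, tukey = tk, pairwise = pw, long = long)
}

#' @rdname pipeline
#' @export
run_reproduce <- function(rc) {
  ds <- run_simulate(rc)
  ds <- run_extract(rc, ds)
  fitted <- run_fit(rc, ds)
  ev <- run_evaluate(rc, fitted$complete, fitted$fit)
  complete <- fitted$complete
  summary <- list(
    seed = rc$seed,
    # hash of the scientific configuration only, so identical studies in
    # different directories produce identical reports
    config_hash = rlang::hash(list(rc$seed, rc$config, rc$spec, rc$alpha)),
    n_records = nrow(ds),
    n_complete = nrow(complete),
    mean_contacts = mean(complete$contacts),
    mean_playing_time_min = mean(complete$playing_time_min),
    mean_rpe = mean(complete$rpe_au),
    mean_srpe = mean(complete$srpe_au),
    zone_means_m = as.list(colMeans(complete[zone_cell_names()])),
    r2_adjusted = fitted$fit$r2_adjusted,
    r2_adjusted_marginal = fitted$fit$r2_adjusted_marginal,
    anova = as.data.frame(ev$anova),
    tukey_significant = ev$tukey$comparison[ev$tukey$significant],
    package_version = as.character(utils::packageVersion("sevensload"))
  )
  jsonlite::write_json(summary,
                       file.path(rc$out_dir, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("reproduce", "summary written to %s",
            file.path(rc$out_dir, "study_summary.json"))
  invisible(list(dataset = ds, complete = complete, fit = fitted$fit,
                 evaluation = ev, summary = summary))
}
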