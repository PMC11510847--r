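#' Read and write the package CSV dialects
#'
#' Plain-CSV serialisation for the three core tables. Traces use columns
#' `time_s, speed_mps, on_field` (0/1), `period` (`H1`/`HT`/`H2`); rosters
#' `athlete_id, mass_kg, sprint_entry_mps`; records one row per
#' player-match with the twelve zone cells, `total_m`, `playing_time_min`,
#' `mass_kg`, `contacts`, `rpe_au`, `srpe_au` and identifiers. Every file
#' round-trips through its own reader without loss of information.
#'
#' @param trace,roster,records Objects to serialise.
#' @param path File path.
#' @param athlete_id,match_id Identifiers to attach when reading a trace.
#' @name sevensload-io
NULL

#' @rdname sevensload-io
#' @export
write_trace_csv <- function(trace, path) {
  validate_speed_trace(trace)
  out <- data.frame(
    time_s = trace$time_s,
    speed_mps = trace$speed_mps,
    on_field = as.integer(trace$on_field),
    period = trace$period
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sevensload-io
#' @export
read_trace_csv <- function(path, athlete_id = NA_character_,
                           match_id = NA_character_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "speed_mps", "on_field", "period")
  if (!all(need %in% names(d))) {
    abort(sprintf("trace file %s lacks columns: %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")),
          class = c("schema_error", "sevensload_error"))
  }
  hz <- 1 / stats::median(diff(d$time_s))
  speed_trace(d$time_s, d$speed_mps, d$on_field == 1, d$period,
              athlete_id = athlete_id, match_id = match_id,
              sample_rate_hz = round(hz))
}

#' @rdname sevensload-io
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(as.data.frame(roster), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname sevensload-io
#' @export
read_roster_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname sevensload-io
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname sevensload-io
#' @export
read_records_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("athlete_id", "match_id", zone_cell_names(), "total_m",
            "playing_time_min", "mass_kg", "contacts", "rpe_au", "srpe_au")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(sprintf("records file %s lacks columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = c("schema_error", "sevensload_error"))
  }
  new_study_dataset(as_tibble(d))
}

#' Serialise a workload fit report
#'
#' Writes the fit as JSON (terms, estimates, SEs, t, df, p, variance
#' components, both adjusted R-squared variants, convergence metadata) and
#' the coefficient table as CSV alongside.
#'
#' @param fit A `workload_fit`.
#' @param json_path Output JSON path.
#' @param csv_path Optional coefficient-table CSV path.
#' @return `json_path`, invisibly.
#' @export
write_fit_report <- function(fit, json_path, csv_path = NULL) {
  stopifnot(inherits(fit, "workload_fit"))
  report <- list(
    coefficients = as.data.frame(fit$coefficients),
    sigma_u_hat = fit$sigma_u_hat,
    sigma_e_hat = fit$sigma_e_hat,
    r2 = fit$r2,
    n_obs = fit$n_obs,
    n_athletes = fit$n_athletes,
    converged = fit$converged,
    standardized = isTRUE(fit$spec$standardize),
    package_version = as.character(utils::packageVersion("sevensload"))
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(fit$coefficients), csv_path,
                     row.names = FALSE)
  }
  invisible(json_path)
}
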