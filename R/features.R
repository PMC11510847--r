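#' Session RPE from its components
#'
#' Session RPE (sRPE) is the product of the athlete's post-match rating of
#' perceived exertion (0-10 scale) and playing time in minutes.
#'
#' @param rpe_au RPE in arbitrary units, 0-10. May contain `NA`.
#' @param playing_time_min Playing time in minutes, >= 0.
#' @return sRPE in arbitrary units; `NA` where RPE is missing.
#' @export
#' @examples
#' compute_srpe(7, 10) # 70
compute_srpe <- function(rpe_au, playing_time_min) {
  if (any(!is.na(rpe_au) & (rpe_au < 0 | rpe_au > 10))) {
    stop_invalid("rpe_au must be within 0-10")
  }
  if (any(is.na(playing_time_min)) || any(playing_time_min < 0)) {
    stop_invalid("playing_time_min must be >= 0")
  }
  if (length(rpe_au) != length(playing_time_min) &&
      length(rpe_au) != 1L && length(playing_time_min) != 1L) {
    stop_invalid("rpe_au and playing_time_min lengths are incompatible")
  }
  rpe_au * playing_time_min
}

model_variable_names <- function() {
  c("mass_kg", "contacts", "playing_time_min", zone_cell_names(),
    "total_m", "rpe_au", "srpe_au")
}

#' Fuse per-source tables into analysis-ready player-match records
#'
#' Joins zone-distance summaries, contact counts, the athlete roster
#' (mass, sprint threshold) and RPE reports into one record per
#' (athlete, match), and computes sRPE where RPE is present.
#'
#' @param zone_summaries Tibble with `athlete_id`, `match_id`, the 12 zone
#'   cells (see [zone_cell_names()]), `total_m`, `playing_time_min`.
#' @param contacts Tibble with `athlete_id`, `match_id`, `contacts`.
#' @param roster Tibble with `athlete_id`, `mass_kg` (and optionally
#'   `sprint_entry_mps`).
#' @param rpe_reports Tibble with `athlete_id`, `match_id`, `rpe_au`
#'   (`NA` = not reported).
#' @param match_meta Tibble with `match_id`, `tournament_id`, `game_number`.
#' @return A `study_dataset`: tibble of player-match records.
#' @export
build_records <- function(zone_summaries, contacts, roster, rpe_reports,
                          match_meta) {
  zs <- as_tibble(zone_summaries)
  key <- paste(zs$athlete_id, zs$match_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_invalid(
      sprintf("duplicate (athlete_id, match_id) pairs in zone summaries: %s",
              paste(unique(gsub("\r", "/", key[duplicated(key)])),
                    collapse = ", ")),
      class = "uniqueness_error"
    )
  }
  missing_ath <- setdiff(zs$athlete_id, roster$athlete_id)
  if (length(missing_ath) > 0) {
    stop_invalid(
      sprintf("athletes present in summaries but absent from roster: %s",
              paste(missing_ath, collapse = ", ")),
      class = "join_error"
    )
  }
  out <- zs |>
    dplyr::left_join(dplyr::select(as_tibble(roster), "athlete_id", "mass_kg"),
                     by = "athlete_id") |>
    dplyr::left_join(
      dplyr::select(as_tibble(contacts), "athlete_id", "match_id", "contacts"),
      by = c("athlete_id", "match_id")
    ) |>
    dplyr::left_join(
      dplyr::select(as_tibble(rpe_reports), "athlete_id", "match_id", "rpe_au"),
      by = c("athlete_id", "match_id")
    ) |>
    dplyr::left_join(
      dplyr::select(as_tibble(match_meta), "match_id", "tournament_id",
                    "game_number"),
      by = "match_id"
    )
  out$srpe_au <- compute_srpe(out$rpe_au, out$playing_time_min)
  front <- c("athlete_id", "match_id", "tournament_id", "game_number")
  out <- out[, c(front, setdiff(names(out), front))]
  new_study_dataset(out)
}

new_study_dataset <- function(records, provenance = NULL) {
  out <- as_tibble(records)
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("study_dataset", class(out)))
  out
}

#' Drop records with any missing model variable
#'
#' Listwise deletion: keeps only records where every variable entering the
#' workload model is present. Counts dropped per field are attached as the
#' `dropped` attribute and reported via a message.
#'
#' @param dataset A `study_dataset` from [build_records()] or
#'   [simulate_study()].
#' @param quiet Suppress the per-field message (default `FALSE`).
#' @return The filtered `study_dataset`.
#' @export
drop_incomplete <- function(dataset, quiet = FALSE) {
  vars <- intersect(model_variable_names(), names(dataset))
  miss <- vapply(dataset[vars], function(x) sum(is.na(x)), integer(1))
  keep <- stats::complete.cases(dataset[vars])
  out <- dataset[keep, ]
  if (nrow(out) == 0L) {
    abort("no complete records remain after listwise deletion",
          class = c("empty_dataset", "sevensload_error"))
  }
  if (!quiet && sum(!keep) > 0) {
    inform(sprintf(
      "dropped %d of %d records (missing: %s)",
      sum(!keep), length(keep),
      paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]),
            collapse = ", ")
    ))
  }
  attr(out, "dropped") <- miss
  new_study_dataset(out, provenance = attr(dataset, "provenance"))
}
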