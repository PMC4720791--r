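#' Write and read the event sheet of a recording
#'
#' The event sheet is a plain CSV with columns `onset_s`, `label`,
#' `run_index`, matching the `events` tibble carried by an `eeg_recording`.
#'
#' @param recording An `eeg_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(recording, path) {
  readr::write_csv(recording$events, path)
  invisible(path)
}

#' @rdname write_events_csv
#' @return For `read_events_csv`, the events tibble.
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    onset_s = readr::col_double(),
    label = readr::col_character(),
    run_index = readr::col_integer()
  ))
}

#' Export a performance grid as TSV
#'
#' One row per condition (task, band, technique) with the pooled TPR, FP/min
#' and detection-latency statistics, mirroring the standard comparison-table
#' layout.
#'
#' @param grid Tibble from [run_condition_grid()] (or bound `cv_result`
#'   summaries).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_performance_tsv <- function(grid, path) {
  readr::write_tsv(grid, path)
  invisible(path)
}

#' Export an MRCP significance profile as TSV
#'
#' @param profile An `mrcp_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path)
  invisible(path)
}
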