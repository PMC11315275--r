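#' Write and read audiograms, trial logs and paired study files
#'
#' All files are plain CSV (comma separator, `"."` decimal, UTF-8, header
#' row, full numeric precision), so results round-trip bit-exactly.
#'
#' @param x A tibble to write (audiogram, trial log, panel export or
#'   paired study table).
#' @param path File path.
#' @return The writers return `path` invisibly; the readers return a
#'   tibble.
#' @export
write_audiogram <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_audiogram
#' @export
read_audiogram <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and validate a paired two-device audiogram file
#'
#' Expects the long format written by [run_two_device_study()] /
#' [write_audiogram()]: columns `participant_id`, `ear`, `device`,
#' `frequency_hz`, `threshold_hl` (extra columns are kept). Validation is
#' row-order independent and rejects: missing columns, frequencies absent
#' from the calibration table, thresholds outside the frequency's
#' measurable range, and duplicate (participant, ear, device, frequency)
#' records — each error lists the offending rows.
#'
#' @param path CSV file path.
#' @param table A [calibration_table] used for range validation.
#' @return A validated long tibble suitable for
#'   [agreement_by_frequency()].
#' @export
read_paired_audiograms <- function(path, table = default_calibration()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("participant_id", "ear", "device", "frequency_hz",
                "threshold_hl")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("paired audiogram file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop("paired audiogram file is empty", call. = FALSE)
  }
  unknown <- !as.integer(round(df$frequency_hz)) %in% table$frequency_hz
  if (any(unknown)) {
    stop("rows ", paste(which(unknown), collapse = ", "),
         ": frequency not in calibration table", call. = FALSE)
  }
  rng <- measurable_range(table, df$frequency_hz)
  bad <- !is.na(df$threshold_hl) &
    (df$threshold_hl < rng$min_hl | df$threshold_hl > rng$max_hl)
  if (any(bad)) {
    stop("rows ", paste(which(bad), collapse = ", "),
         ": threshold outside the measurable range at that frequency",
         call. = FALSE)
  }
  key <- paste(df$participant_id, df$ear, df$device, df$frequency_hz)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("rows ", paste(which(dup), collapse = ", "),
         ": duplicate (participant, ear, device, frequency) records",
         call. = FALSE)
  }
  df
}

#' Export per-frequency agreement results
#'
#' Writes the per-frequency table as CSV (list-columns dropped) and, when
#' `json_path` is given, a JSON summary combining the across-frequency
#' and pooled statistics.
#'
#' @param by_freq An `agreement_by_freq` tibble.
#' @param path CSV output path.
#' @param json_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(by_freq, path, json_path = NULL) {
  flat <- dplyr::select(tibble::as_tibble(by_freq), "frequency_hz", "n",
                        "bias_db", "sd_db", "loa_low_db", "loa_high_db")
  readr::write_csv(flat, path)
  if (!is.null(json_path)) {
    summary <- summarize_agreement(by_freq)
    jsonlite::write_json(as.list(summary), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
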