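#' Calibration tables: dB HL, digital amplification and dB SPL
#'
#' A calibration table relates, for each test frequency, the hearing level
#' scale (dB HL) to the digital amplification of the synthesised signal and
#' to the acoustic output (dB SPL) through the transducer's RETSPL
#' (Reference Equivalent Threshold Sound Pressure Level, the SPL that
#' corresponds to 0 dB HL). The device presents tones at digital
#' amplifications between `amp_min_db` and `amp_max_db` on an `amp_step_db`
#' grid; `ref_amplification_db` is the amplification that produces 0 dB HL,
#' so `amplification = ref_amplification_db + level_hl`. When a listener
#' gives no response at the maximum presentable level, the recorded
#' threshold is that level plus `ceiling_bonus_db`.
#'
#' @param entries A data frame with columns `frequency_hz` (positive,
#'   unique), `retspl_db_spl`, `ref_amplification_db` (within the
#'   amplification bounds) and optionally `extrapolated` (logical; `TRUE`
#'   for rows whose RETSPL was extrapolated from the output measured at
#'   maximum amplification because 70 dB HL was not reachable before
#'   saturation).
#' @param amp_min_db,amp_max_db,amp_step_db Digital amplification bounds
#'   and step, in dB. Amplification 0 is digital silence and is not part of
#'   the presentable grid. Defaults 5, 100 and 5.
#' @param ceiling_bonus_db dB added to the maximum presentable hearing
#'   level when recording a no-response ceiling. Default 5.
#'
#' @return A tibble of class `calibration_table` with one row per
#'   frequency, carrying the amplification bounds as attributes.
#' @seealso [default_calibration()], [hl_to_amplification()],
#'   [measurable_range()]
#' @export
calibration_table <- function(entries, amp_min_db = 5, amp_max_db = 100,
                              amp_step_db = 5, ceiling_bonus_db = 5) {
  stopifnot(is.data.frame(entries))
  required <- c("frequency_hz", "retspl_db_spl", "ref_amplification_db")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    stop("calibration entries lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"extrapolated" %in% names(entries)) entries$extrapolated <- FALSE
  tbl <- tibble::as_tibble(entries[, c(required, "extrapolated")])
  tbl$frequency_hz <- as.integer(round(tbl$frequency_hz))
  if (anyDuplicated(tbl$frequency_hz)) {
    stop("duplicate frequencies in calibration table", call. = FALSE)
  }
  if (any(tbl$frequency_hz <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (!(amp_min_db > 0)) stop("amp_min_db must be > 0", call. = FALSE)
  if (!(amp_max_db > amp_min_db)) {
    stop("amp_max_db must exceed amp_min_db", call. = FALSE)
  }
  if (abs((amp_max_db - amp_min_db) %% amp_step_db) > 1e-9) {
    stop("amp_step_db must divide (amp_max_db - amp_min_db)", call. = FALSE)
  }
  bad <- tbl$ref_amplification_db < amp_min_db |
    tbl$ref_amplification_db > amp_max_db
  if (any(bad)) {
    stop("reference amplification out of [", amp_min_db, ", ", amp_max_db,
         "] dB at ", paste(tbl$frequency_hz[bad], collapse = ", "), " Hz",
         call. = FALSE)
  }
  structure(tbl,
            amp_min_db = amp_min_db, amp_max_db = amp_max_db,
            amp_step_db = amp_step_db, ceiling_bonus_db = ceiling_bonus_db,
            class = c("calibration_table", class(tibble::tibble())))
}

#' Default calibration table (DT-770 Pro transducer, 15 frequencies)
#'
#' The packaged calibration covers 0.125-16 kHz: per-frequency RETSPL and
#' the digital amplification producing 0 dB HL, as established for the
#' Beyerdynamic DT-770 Pro 32-ohm headphones after perceptual calibration
#' against a clinical audiometer. RETSPLs at 0.125, 14 and 16 kHz are
#' extrapolated from the output measured at maximum amplification
#' (70 dB HL not being reachable before digital saturation there) and are
#' flagged `extrapolated`.
#'
#' @return A `calibration_table` with 15 rows.
#' @examples
#' tab <- default_calibration()
#' measurable_range(tab, 1000)
#' @export
default_calibration <- function() {
  calibration_table(tibble::tibble(
    frequency_hz = c(125L, 250L, 500L, 750L, 1000L, 1500L, 2000L, 3000L,
                     4000L, 6000L, 8000L, 10000L, 12500L, 14000L, 16000L),
    retspl_db_spl = c(37.2, 19.6, 12.5, 7.4, 7.5, 6.1, 7.9, 6.3, -3.9,
                      22.8, 23.0, 27.5, 26.7, 33.3, 52.8),
    ref_amplification_db = c(35, 30, 20, 15, 15, 15, 15, 15, 15, 20, 15,
                             25, 25, 35, 50),
    extrapolated = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ))
}

cal_attr <- function(table, which) attr(table, which, exact = TRUE)

cal_lookup <- function(table, frequency_hz) {
  idx <- match(as.integer(round(frequency_hz)), table$frequency_hz)
  if (anyNA(idx)) {
    stop("frequency ", paste(frequency_hz[is.na(idx)], collapse = ", "),
         " Hz not in calibration table", call. = FALSE)
  }
  idx
}

#' Convert hearing level to digital amplification
#'
#' `amplification = ref_amplification_db + level_hl`. The result must land
#' on the device's amplification grid and within its bounds; anything else
#' is an error naming the violated constraint, because such a level cannot
#' be presented.
#'
#' @param table A [calibration_table].
#' @param frequency_hz Test frequency (must be in the table). Vectorised.
#' @param level_hl Hearing level in dB HL. Vectorised.
#' @return Digital amplification in dB.
#' @examples
#' tab <- default_calibration()
#' hl_to_amplification(tab, 1000, 70)  # 85
#' @export
hl_to_amplification <- function(table, frequency_hz, level_hl) {
  idx <- cal_lookup(table, frequency_hz)
  amp <- table$ref_amplification_db[idx] + level_hl
  amp_min <- cal_attr(table, "amp_min_db")
  amp_max <- cal_attr(table, "amp_max_db")
  step <- cal_attr(table, "amp_step_db")
  if (any(amp < amp_min - 1e-9)) {
    stop("amplification ", min(amp), " dB below minimum ", amp_min, " dB",
         call. = FALSE)
  }
  if (any(amp > amp_max + 1e-9)) {
    stop("amplification ", max(amp), " dB above maximum ", amp_max, " dB",
         call. = FALSE)
  }
  off <- abs(amp / step - round(amp / step)) > 1e-9
  if (any(off)) {
    stop("amplification ", paste(amp[off], collapse = ", "),
         " dB not on the ", step, "-dB grid", call. = FALSE)
  }
  amp
}

#' Convert digital amplification back to hearing level
#'
#' Inverse of [hl_to_amplification()].
#'
#' @inheritParams hl_to_amplification
#' @param amplification_db Digital amplification in dB.
#' @return Hearing level in dB HL.
#' @export
amplification_to_hl <- function(table, frequency_hz, amplification_db) {
  idx <- cal_lookup(table, frequency_hz)
  amplification_db - table$ref_amplification_db[idx]
}

#' Convert hearing level to expected sound pressure level
#'
#' `spl = retspl + level_hl`: the coupler SPL expected when presenting
#' `level_hl` at `frequency_hz`, used to check calibration with an
#' artificial ear (conventionally at 70 dB HL).
#'
#' @inheritParams hl_to_amplification
#' @return Expected SPL in dB.
#' @examples
#' hl_to_spl(default_calibration(), 6000, 70)  # 92.8
#' @export
hl_to_spl <- function(table, frequency_hz, level_hl) {
  idx <- cal_lookup(table, frequency_hz)
  table$retspl_db_spl[idx] + level_hl
}

#' Convert digital amplification to linear digital amplitude
#'
#' The digital amplification scale places 100 dB at full scale (amplitude
#' 1) and maps down logarithmically: `amplitude = 10^((A - 100) / 20)`.
#' Amplification 0 is special-cased to exact digital silence, since the
#' logarithmic map would give 1e-5 rather than 0.
#'
#' @param amplification_db Digital amplification in dB: 0, or within
#'   `[amp_min_db, amp_max_db]`. Vectorised.
#' @param amp_max_db Upper bound of the scale (default 100).
#' @return Linear amplitude in `[0, 1]`, applied as the sine's peak scale
#'   factor.
#' @examples
#' amplification_to_amplitude(c(0, 80, 100))  # 0, 0.1, 1
#' @export
amplification_to_amplitude <- function(amplification_db, amp_max_db = 100) {
  if (any(amplification_db < 0)) {
    stop("amplification must be >= 0 dB", call. = FALSE)
  }
  if (any(amplification_db > amp_max_db)) {
    stop("amplification above maximum ", amp_max_db, " dB", call. = FALSE)
  }
  ifelse(amplification_db == 0, 0,
         10^((amplification_db - amp_max_db) / 20))
}

#' Measurable audiometric range at each frequency
#'
#' The minimum presentable hearing level corresponds to the minimum
#' nonzero amplification; the maximum recordable level is the level at
#' maximum amplification plus the no-response ceiling bonus:
#' `min_hl = amp_min - ref_amp`, `max_hl = amp_max - ref_amp +
#' ceiling_bonus`.
#'
#' @param table A [calibration_table].
#' @param frequency_hz Frequencies to report; defaults to all in the table.
#' @return A tibble with columns `frequency_hz`, `min_hl`, `max_hl`
#'   (dB HL).
#' @examples
#' measurable_range(default_calibration(), c(1000, 16000))
#' @export
measurable_range <- function(table, frequency_hz = table$frequency_hz) {
  idx <- cal_lookup(table, frequency_hz)
  ref <- table$ref_amplification_db[idx]
  tibble::tibble(
    frequency_hz = table$frequency_hz[idx],
    min_hl = cal_attr(table, "amp_min_db") - ref,
    max_hl = cal_attr(table, "amp_max_db") - ref +
      cal_attr(table, "ceiling_bonus_db")
  )
}

# Range of levels that can actually be emitted (max excludes the ceiling
# recording bonus).
presentable_range <- function(table, frequency_hz) {
  r <- measurable_range(table, frequency_hz)
  r$max_hl <- r$max_hl - cal_attr(table, "ceiling_bonus_db")
  r
}

#' Extrapolate a RETSPL from the output measured at maximum amplification
#'
#' At frequencies where the conventional 70 dB HL calibration point is not
#' reachable before digital saturation, the SPL is measured at the maximum
#' amplification and the RETSPL estimated by subtracting the hearing level
#' reachable there: `retspl = measured_spl - (amp_max - ref_amp)`.
#'
#' @param measured_spl_at_max SPL (dB) measured at `amp_max_db`.
#' @param ref_amplification_db Amplification producing 0 dB HL.
#' @param amp_max_db Maximum digital amplification (default 100).
#' @return Estimated RETSPL in dB SPL.
#' @examples
#' estimate_retspl_from_ceiling(102.8, 50)  # 52.8
#' @export
estimate_retspl_from_ceiling <- function(measured_spl_at_max,
                                         ref_amplification_db,
                                         amp_max_db = 100) {
  if (any(ref_amplification_db > amp_max_db)) {
    stop("reference amplification exceeds amp_max_db", call. = FALSE)
  }
  measured_spl_at_max - (amp_max_db - ref_amplification_db)
}

# Round half away from zero to the nearest multiple of `unit`; symmetric
# treatment of positive and negative biases.
round_to_multiple <- function(x, unit = 5) {
  unit * sign(x) * floor(abs(x) / unit + 0.5)
}

#' Adjust a calibration from measured inter-device differences
#'
#' Post-hoc calibration step: the mean threshold difference per frequency
#' between this device and a reference device is rounded to the nearest
#' multiple of 5 dB (half away from zero) and applied to the reference
#' amplification; frequencies whose rounded deviation is 0 are unchanged.
#' Returns a new table, leaving the original untouched.
#'
#' @param table A [calibration_table].
#' @param mean_diff A data frame with columns `frequency_hz` and
#'   `mean_diff_db`, or a single number applied to every frequency. Its
#'   frequency set must match the table's exactly.
#' @return A new `calibration_table`.
#' @examples
#' adjust_calibration(default_calibration(), -0.63)  # rounds to 0: unchanged
#' @export
adjust_calibration <- function(table, mean_diff) {
  if (is.numeric(mean_diff) && length(mean_diff) == 1) {
    mean_diff <- tibble::tibble(frequency_hz = table$frequency_hz,
                                mean_diff_db = mean_diff)
  }
  stopifnot(is.data.frame(mean_diff),
            all(c("frequency_hz", "mean_diff_db") %in% names(mean_diff)))
  freqs <- as.integer(round(mean_diff$frequency_hz))
  if (!setequal(freqs, table$frequency_hz) ||
      length(freqs) != nrow(table)) {
    stop("mean_diff must give exactly one difference per table frequency",
         call. = FALSE)
  }
  shift <- round_to_multiple(mean_diff$mean_diff_db[match(table$frequency_hz,
                                                          freqs)])
  out <- tibble::as_tibble(table)
  out$ref_amplification_db <- out$ref_amplification_db + shift
  calibration_table(out,
                    amp_min_db = cal_attr(table, "amp_min_db"),
                    amp_max_db = cal_attr(table, "amp_max_db"),
                    amp_step_db = cal_attr(table, "amp_step_db"),
                    ceiling_bonus_db = cal_attr(table, "ceiling_bonus_db"))
}

#' Read / write a calibration table as CSV
#'
#' Columns `frequency_hz`, `retspl_db_spl`, `ref_amplification_db`,
#' `extrapolated`. The amplification bounds are not stored in the CSV and
#' are supplied on read.
#'
#' @param path File path.
#' @inheritParams calibration_table
#' @return `read_calibration()` returns a `calibration_table`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path, amp_min_db = 5, amp_max_db = 100,
                             amp_step_db = 5, ceiling_bonus_db = 5) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  calibration_table(df, amp_min_db = amp_min_db, amp_max_db = amp_max_db,
                    amp_step_db = amp_step_db,
                    ceiling_bonus_db = ceiling_bonus_db)
}

#' @rdname read_calibration
#' @param table A `calibration_table` to write.
#' @export
write_calibration <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}
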