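# Shared fixtures: the printed calibration reference and small listeners.

# The published per-frequency calibration: RETSPL, reference amplification,
# the SPL measured at the calibration level, and the printed audiometric
# range. The printed range at 8 kHz ([-15, 90]) is inconsistent with its
# reference amplification (15 dB implies [-10, 90]); tests treat that row
# separately.
printed_calibration <- tibble::tibble(
  frequency_hz = c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000,
                   6000, 8000, 10000, 12500, 14000, 16000),
  retspl_db_spl = c(37.2, 19.6, 12.5, 7.4, 7.5, 6.1, 7.9, 6.3, -3.9,
                    22.8, 23.0, 27.5, 26.7, 33.3, 52.8),
  ref_amplification_db = c(35, 30, 20, 15, 15, 15, 15, 15, 15, 20, 15,
                           25, 25, 35, 50),
  measured_spl = c(102.2, 89.6, 82.5, 77.4, 77.5, 76.1, 77.9, 76.3, 66.1,
                   92.8, 93.0, 97.5, 96.7, 98.3, 102.8),
  # SPL above was measured at 70 dB HL, except the starred rows measured
  # at maximum amplification (100 dB)
  measured_at_max = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                      TRUE),
  range_min = c(-30, -25, -15, -10, -10, -10, -10, -10, -10, -15, -15,
                -20, -20, -30, -45),
  range_max = c(70, 75, 85, 90, 90, 90, 90, 90, 90, 85, 90, 80, 80, 70,
                55)
)

det_listener_at <- function(frequency_hz, threshold_hl) {
  deterministic_listener(stats::setNames(threshold_hl, frequency_hz))
}

# Closed-form oracle for a deterministic step listener: the staircase's
# ascending detection lands on the smallest 5-dB grid level at or above
# the true threshold, clipped to the measurable bounds.
oracle_threshold <- function(true_hl, min_hl, max_hl) {
  grid <- ceiling(true_hl / 5) * 5
  if (grid < min_hl) return(min_hl)          # floor recording
  if (grid > max_hl - 5) return(max_hl)      # ceiling recording (+5 rule)
  grid
}
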