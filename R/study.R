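#' Specify a simulated study panel
#'
#' Describes a panel of listeners measured on two devices, emulating a
#' perceptual validation study: participants with clinically normal
#' hearing (thresholds below 25 dB HL from 0.25 to 8 kHz in both ears),
#' split into a young and an elderly group, the elderly carrying
#' age-related extended-high-frequency loss of up to `ehf_loss_max_hl`
#' dB HL at 14-16 kHz. The two "devices" differ by per-frequency
#' calibration offsets, and every track carries independent session
#' noise.
#'
#' @param n_participants Number of participants, two ears each
#'   (default 16).
#' @param n_young Participants in the young group (default 7; the
#'   remaining `n_participants - n_young` are elderly).
#' @param normal_mean_hl,normal_sd_hl Normal-hearing threshold
#'   distribution, dB HL (defaults 5 and 5); draws at 0.25-8 kHz that
#'   reach 25 dB HL are resampled.
#' @param ehf_loss_max_hl Maximum elderly high-frequency loss, dB HL at
#'   16 kHz (default 65). Per-ear severity is drawn uniformly on
#'   `[20, ehf_loss_max_hl]` and ramped in over 10-16 kHz.
#' @param device_offset_db Per-frequency calibration offset of device B
#'   relative to device A: a single number or a vector named by frequency
#'   (default 0).
#' @param session_noise_sd_db SD of the independent per-track threshold
#'   noise, dB (default 3).
#' @param slope_db,guess_rate,lapse_rate Listener psychometric
#'   parameters, passed to [listener_model()].
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_participants = 16,
                       n_young = min(7, n_participants),
                       normal_mean_hl = 5, normal_sd_hl = 5,
                       ehf_loss_max_hl = 65,
                       device_offset_db = 0,
                       session_noise_sd_db = 3,
                       slope_db = 4, guess_rate = 0.01, lapse_rate = 0.02) {
  stopifnot(n_participants >= 0, n_young >= 0, n_young <= n_participants,
            normal_sd_hl >= 0, ehf_loss_max_hl >= 0,
            session_noise_sd_db >= 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_young = as.integer(n_young),
                 normal_mean_hl = normal_mean_hl,
                 normal_sd_hl = normal_sd_hl,
                 ehf_loss_max_hl = ehf_loss_max_hl,
                 device_offset_db = device_offset_db,
                 session_noise_sd_db = session_noise_sd_db,
                 slope_db = slope_db, guess_rate = guess_rate,
                 lapse_rate = lapse_rate),
            class = "panel_spec")
}

# Fraction of the full EHF loss applied at each frequency for the elderly
# profile: none at or below 8 kHz, ramping to the full severity at 16 kHz.
ehf_loss_ramp <- function(frequency_hz) {
  ramp <- c("10000" = 0.25, "12500" = 0.5, "14000" = 0.85, "16000" = 1)
  out <- ramp[as.character(as.integer(round(frequency_hz)))]
  out[is.na(out)] <- 0
  unname(out)
}

sample_ear_thresholds <- function(spec, group, frequencies) {
  thr <- stats::rnorm(length(frequencies), spec$normal_mean_hl,
                      spec$normal_sd_hl)
  # inclusion criterion: normal hearing (< 25 dB HL) from 0.25 to 8 kHz
  normal_band <- frequencies >= 250 & frequencies <= 8000
  while (any(bad <- normal_band & thr >= 25)) {
    thr[bad] <- stats::rnorm(sum(bad), spec$normal_mean_hl,
                             spec$normal_sd_hl)
  }
  if (group == "elderly" && spec$ehf_loss_max_hl > 0) {
    severity <- stats::runif(1, min(20, spec$ehf_loss_max_hl),
                             spec$ehf_loss_max_hl)
    thr <- thr + severity * ehf_loss_ramp(frequencies)
  }
  stats::setNames(thr, frequencies)
}

#' Generate a simulated study panel
#'
#' Draws true per-ear thresholds for every participant (young group:
#' normal hearing throughout; elderly group: normal up to 8 kHz plus an
#' extended-high-frequency loss ramp), builds a [listener_model()] per
#' ear, and assigns the device order alternately across participants
#' (counterbalancing).
#'
#' @param spec A [panel_spec].
#' @param table A [calibration_table] supplying the frequencies.
#' @param seed Optional integer seed; a given seed reproduces the panel
#'   bit-for-bit.
#' @return A tibble with one row per ear: `participant_id`, `ear`
#'   (`"left"`/`"right"`), `group`, `device_order` (`"AB"`/`"BA"`), and a
#'   `listener` list-column.
#' @examples
#' panel <- generate_panel(panel_spec(), default_calibration(), seed = 1)
#' nrow(panel)  # 32 ears
#' @export
generate_panel <- function(spec, table, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frequencies <- table$frequency_hz
  if (spec$n_participants == 0) {
    return(tibble::tibble(participant_id = integer(0),
                          ear = character(0), group = character(0),
                          device_order = character(0),
                          listener = list()))
  }
  groups <- c(rep("young", spec$n_young),
              rep("elderly", spec$n_participants - spec$n_young))
  rows <- purrr::map(seq_len(spec$n_participants), function(p) {
    purrr::map(c("left", "right"), function(e) {
      thr <- sample_ear_thresholds(spec, groups[p], frequencies)
      tibble::tibble(
        participant_id = p, ear = e, group = groups[p],
        device_order = if (p %% 2 == 1) "AB" else "BA",
        listener = list(listener_model(
          thr, slope_db = spec$slope_db, guess_rate = spec$guess_rate,
          lapse_rate = spec$lapse_rate)))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

device_offsets_for <- function(spec, frequencies) {
  off <- spec$device_offset_db
  if (length(off) == 1 && is.null(names(off))) {
    return(stats::setNames(rep(off, length(frequencies)), frequencies))
  }
  out <- off[as.character(as.integer(round(frequencies)))]
  out[is.na(out)] <- 0
  stats::setNames(unname(out), frequencies)
}

perturbed_listener <- function(listener, shift_db) {
  listener$true_threshold_hl <- listener$true_threshold_hl + shift_db
  listener
}

#' Run a simulated two-device study
#'
#' Measures every ear of a panel on two devices: device A uses the
#' listener's true thresholds; device B shifts each effective threshold
#' by the panel's per-frequency calibration offset. Every ear-device
#' session additionally perturbs the effective thresholds with
#' independent Gaussian session noise, so repeated tracks scatter as real
#' test-retest audiometry does. Device order follows the panel's
#' counterbalanced assignment.
#'
#' @param panel A panel tibble from [generate_panel()].
#' @param config_a,config_b [procedure_config()]s for devices A and B
#'   (defaults: the Aupiometer-variant procedure for both).
#' @param table A [calibration_table].
#' @param seed Optional integer seed.
#' @param spec The [panel_spec()] that generated the panel (supplies the
#'   device offsets and session-noise SD).
#' @return A long tibble: `participant_id`, `ear`, `group`, `device`
#'   (`"A"`/`"B"`), `frequency_hz`, `threshold_hl`, `status`, `n_trials`.
#' @export
run_two_device_study <- function(panel, table, spec = panel_spec(),
                                 config_a = procedure_config("aupiometer"),
                                 config_b = procedure_config("aupiometer"),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frequencies <- table$frequency_hz
  offsets <- device_offsets_for(spec, frequencies)
  out <- purrr::map(seq_len(nrow(panel)), function(i) {
    base <- panel$listener[[i]]
    devices <- if (panel$device_order[i] == "AB") c("A", "B") else c("B", "A")
    purrr::map(devices, function(dev) {
      shift <- stats::rnorm(length(frequencies), 0,
                            spec$session_noise_sd_db)
      if (dev == "B") shift <- shift + offsets
      eff <- perturbed_listener(base, stats::setNames(shift, frequencies))
      cfg <- if (dev == "A") config_a else config_b
      res <- run_session(eff, cfg, table, keep_trials = FALSE)
      tibble::tibble(participant_id = panel$participant_id[i],
                     ear = panel$ear[i], group = panel$group[i],
                     device = dev, frequency_hz = res$frequency_hz,
                     threshold_hl = res$threshold_hl,
                     status = res$status, n_trials = res$n_trials)
    })
  })
  dplyr::bind_rows(purrr::flatten(out))
}
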