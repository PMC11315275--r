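#' Configure the adaptive threshold procedure
#'
#' The automated Hughson-Westlake track starts at 40 dB HL, descends 10 dB
#' after each detection and ascends 5 dB after each miss (no press, or a
#' press after the response window). A threshold is validated on a correct
#' detection once enough staircase inversions (direction reversals) have
#' occurred; the required count depends on how the track starts and on the
#' device variant:
#'
#' * descending start (first trial detected): 2 inversions — an omission
#'   then a correct detection — for both variants;
#' * ascending start (first trial missed): 3 inversions for the
#'   `"aupiometer"` variant (double validation), 1 for the `"elios"`
#'   variant (the first correct detection).
#'
#' The variants also differ in that the ELIOS stops the stimulus on press
#' while the Aupiometer always plays the full train; this affects trial
#' timing only, never level sequencing.
#'
#' @param variant `"aupiometer"` or `"elios"`.
#' @param start_level_hl Starting level, dB HL (default 40).
#' @param step_down_db,step_up_db Step sizes in dB (defaults 10 and 5).
#' @param iti_min_ms,iti_max_ms Bounds of the uniformly drawn inter-trial
#'   pause (defaults 2000 and 4000 ms).
#' @param response_window_ms Presses later than this count as misses
#'   (default 2000 ms, the stimulus duration).
#' @param max_trials Safety cap per track; exceeding it aborts the track
#'   (default 50).
#' @param frequency_order_hz Session test order. Default: 1, 1.5, 2, 3, 4,
#'   6, 8, 10, 12.5, 14, 16 kHz then 0.75, 0.5, 0.25, 0.125 kHz.
#' @return An object of class `procedure_config`.
#' @export
procedure_config <- function(variant = c("aupiometer", "elios"),
                             start_level_hl = 40,
                             step_down_db = 10, step_up_db = 5,
                             iti_min_ms = 2000, iti_max_ms = 4000,
                             response_window_ms = 2000,
                             max_trials = 50,
                             frequency_order_hz = c(1000, 1500, 2000, 3000,
                                                    4000, 6000, 8000, 10000,
                                                    12500, 14000, 16000,
                                                    750, 500, 250, 125)) {
  variant <- match.arg(variant)
  stopifnot(step_down_db > 0, step_up_db > 0, iti_min_ms <= iti_max_ms,
            max_trials >= 1)
  structure(list(
    variant = variant,
    start_level_hl = start_level_hl,
    step_down_db = step_down_db,
    step_up_db = step_up_db,
    iti_min_ms = iti_min_ms,
    iti_max_ms = iti_max_ms,
    response_window_ms = response_window_ms,
    inversions_descending_start = 2L,
    inversions_ascending_start = if (variant == "aupiometer") 3L else 1L,
    stop_on_press = variant == "elios",
    max_trials = as.integer(max_trials),
    frequency_order_hz = frequency_order_hz
  ), class = "procedure_config")
}

#' @export
print.procedure_config <- function(x, ...) {
  cat(sprintf(
    "<procedure_config> %s: start %g dB HL, -%g/+%g dB, ITI %g-%g ms, inversions %d (descending) / %d (ascending start), max %d trials\n",
    x$variant, x$start_level_hl, x$step_down_db, x$step_up_db,
    x$iti_min_ms, x$iti_max_ms, x$inversions_descending_start,
    x$inversions_ascending_start, x$max_trials))
  invisible(x)
}

#' Initialise a staircase
#'
#' @param config A [procedure_config].
#' @param range One row of [measurable_range()] for the tested frequency
#'   (a list or one-row data frame with `min_hl` and `max_hl`).
#' @param ceiling_bonus_db dB added on a no-response ceiling; `range$max_hl`
#'   already includes it, so the maximum presentable level is
#'   `max_hl - ceiling_bonus_db`.
#' @return An object of class `staircase_state` with status `"running"`.
#' @export
new_staircase <- function(config, range, ceiling_bonus_db = 5) {
  p_max <- range$max_hl - ceiling_bonus_db
  start <- min(max(config$start_level_hl, range$min_hl), p_max)
  structure(list(
    current_level_hl = start,
    direction = "none",
    inversion_count = 0L,
    first_trial_outcome = "unset",
    min_hl = range$min_hl,
    max_hl = range$max_hl,
    presentable_max_hl = p_max,
    n_trials = 0L,
    n_detections_at_min = 0L,
    status = "running",
    threshold_hl = NA_real_,
    trial_level = numeric(0),
    trial_response = logical(0),
    trial_latency = numeric(0),
    trial_iti = numeric(0)
  ), class = "staircase_state")
}

#' Level for the next trial
#'
#' After a detection the level drops by `step_down_db`; after a miss it
#' rises by `step_up_db`; the result is clipped to the presentable range
#' (the ceiling bonus is a recording rule, not a presentable level).
#'
#' @param state A running `staircase_state`.
#' @param config A [procedure_config].
#' @return The level (dB HL) to present next.
#' @export
next_level <- function(state, config) {
  if (state$status != "running") {
    stop("staircase already terminated (", state$status, ")", call. = FALSE)
  }
  if (state$n_trials == 0L) return(state$current_level_hl)
  last_resp <- state$trial_response[state$n_trials]
  lvl <- state$current_level_hl +
    if (last_resp) -config$step_down_db else config$step_up_db
  min(max(lvl, state$min_hl), state$presentable_max_hl)
}

#' Record a trial and advance the staircase
#'
#' Pure transition: appends the trial, tracks direction and inversions,
#' and applies the terminal rules — validation on a correct detection at
#' the required inversion count, ceiling (recorded threshold =
#' `max_hl`, i.e. presentable max + 5 dB) on a miss at the maximum
#' presentable level, floor on a second consecutive detection at the
#' minimum level, abort past `max_trials`.
#'
#' @param state A running `staircase_state`.
#' @param level_hl Level presented on this trial.
#' @param response `TRUE` if the press counts as a detection (on time).
#' @param config A [procedure_config].
#' @param latency_ms,iti_ms Optional timing bookkeeping, kept in the
#'   history.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, level_hl, response, config,
                             latency_ms = NA_real_, iti_ms = NA_real_) {
  if (state$status != "running") {
    stop("staircase already terminated (", state$status, ")", call. = FALSE)
  }
  n <- state$n_trials + 1L
  state$n_trials <- n
  state$trial_level[n] <- level_hl
  state$trial_response[n] <- response
  state$trial_latency[n] <- latency_ms
  state$trial_iti[n] <- iti_ms
  state$current_level_hl <- level_hl

  new_dir <- if (response) "down" else "up"
  if (n == 1L) {
    state$first_trial_outcome <- if (response) "detected" else "missed"
    state$direction <- new_dir
  } else if (new_dir != state$direction) {
    state$inversion_count <- state$inversion_count + 1L
    state$direction <- new_dir
  }
  state$n_detections_at_min <-
    if (response && level_hl <= state$min_hl) {
      state$n_detections_at_min + 1L
    } else 0L

  required <- if (state$first_trial_outcome == "detected") {
    config$inversions_descending_start
  } else {
    config$inversions_ascending_start
  }
  if (response && state$inversion_count >= required) {
    state$status <- "validated"
    state$threshold_hl <- level_hl
  } else if (!response && level_hl >= state$presentable_max_hl) {
    state$status <- "ceiling"
    state$threshold_hl <- state$max_hl
  } else if (state$n_detections_at_min >= 2L) {
    state$status <- "floor"
    state$threshold_hl <- state$min_hl
  } else if (n >= config$max_trials) {
    state$status <- "aborted"
  }
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> %s after %d trial(s): level %g dB HL, %d inversion(s), threshold %s\n",
    x$status, x$n_trials, x$current_level_hl, x$inversion_count,
    if (is.na(x$threshold_hl)) "NA" else paste0(x$threshold_hl, " dB HL")))
  invisible(x)
}

#' Run one threshold track against a listener
#'
#' Drives [next_level()] / [update_staircase()] at one frequency until the
#' track terminates, presenting levels to the listener callback and
#' drawing each inter-trial interval uniformly from
#' `[iti_min_ms, iti_max_ms]` with the session's random generator. Presses
#' later than `response_window_ms` are recorded as misses with the latency
#' kept.
#'
#' @param listener A [listener_model()].
#' @param frequency_hz Tested frequency (must be in `table`).
#' @param config A [procedure_config].
#' @param table A [calibration_table].
#' @param keep_trials Keep the per-trial history? (default `TRUE`;
#'   disable in large simulations).
#' @return A one-row tibble (`frequency_hz`, `threshold_hl`, `status`,
#'   `n_trials`), with the trial history tibble as attribute `"trials"`
#'   when kept.
#' @examples
#' tab <- default_calibration()
#' cfg <- procedure_config("aupiometer")
#' run_track(deterministic_listener(c("1000" = 20)), 1000, cfg, tab)
#' @export
run_track <- function(listener, frequency_hz, config, table,
                      keep_trials = TRUE) {
  range <- measurable_range(table, frequency_hz)
  state <- new_staircase(config, range,
                         ceiling_bonus_db = attr(table, "ceiling_bonus_db"))
  while (state$status == "running") {
    lvl <- next_level(state, config)
    ans <- respond(listener, lvl, frequency_hz)
    on_time <- ans$pressed && ans$latency_ms <= config$response_window_ms
    iti <- stats::runif(1, config$iti_min_ms, config$iti_max_ms)
    state <- update_staircase(state, lvl, on_time, config,
                              latency_ms = if (ans$pressed) ans$latency_ms
                                           else NA_real_,
                              iti_ms = iti)
  }
  res <- tibble::tibble(frequency_hz = range$frequency_hz,
                        threshold_hl = state$threshold_hl,
                        status = state$status,
                        n_trials = state$n_trials)
  if (keep_trials) {
    attr(res, "trials") <- tibble::tibble(
      frequency_hz = range$frequency_hz,
      trial_index = seq_len(state$n_trials),
      level_hl = state$trial_level,
      amplification_db = hl_to_amplification(table, range$frequency_hz,
                                             state$trial_level),
      response = state$trial_response,
      latency_ms = state$trial_latency,
      iti_ms = state$trial_iti)
  }
  res
}

#' Run a full audiometric session (one ear)
#'
#' Runs [run_track()] over `config$frequency_order_hz`, in order. With a
#' seed the whole session is reproducible bit-for-bit.
#'
#' @inheritParams run_track
#' @param seed Optional integer seed for the session's random generator.
#' @return An audiogram tibble (one row per frequency: `frequency_hz`,
#'   `threshold_hl`, `status`, `n_trials`), with the concatenated trial
#'   log as attribute `"trials"` when kept.
#' @examples
#' tab <- default_calibration()
#' listener <- deterministic_listener(flat_thresholds(10, tab))
#' run_session(listener, procedure_config("elios"), tab)
#' @export
run_session <- function(listener, config, table, seed = NULL,
                        keep_trials = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  tracks <- lapply(config$frequency_order_hz, function(f) {
    run_track(listener, f, config, table, keep_trials = keep_trials)
  })
  out <- dplyr::bind_rows(tracks)
  if (keep_trials) {
    attr(out, "trials") <- dplyr::bind_rows(lapply(tracks, attr, "trials"))
  }
  out
}
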