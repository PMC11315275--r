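#' Simulated psychometric listener
#'
#' An observer whose probability of pressing the response button at level
#' `L` and frequency `f` follows a psychometric function
#' `P(press) = guess + (1 - guess - lapse) * F((L - T_f) / sigma)`,
#' where `T_f` is the true threshold at `f`, `sigma` the psychometric
#' spread and `F` the standard normal (or logistic) CDF. Response latency
#' is log-normal; a press whose latency exceeds the response window is
#' scored downstream as a miss ("too late"), so late presses emerge from
#' the latency distribution rather than a separate parameter.
#'
#' @param true_threshold_hl Named numeric vector (names = frequency in
#'   Hz) or data frame with columns `frequency_hz`, `threshold_hl`.
#' @param slope_db Psychometric spread sigma in dB (default 4). `0` gives
#'   a deterministic step observer (press iff level >= threshold).
#' @param guess_rate,lapse_rate False-alarm floor and inattention ceiling
#'   of the psychometric function (defaults 0.01 and 0.02;
#'   `guess + lapse < 1`).
#' @param latency_median_ms Median press latency (default 600 ms).
#' @param latency_sigma_log Log-scale SD of the latency distribution
#'   (default 0.35). `0` gives fixed latency.
#' @param psychometric `"normal"` (default) or `"logistic"` link.
#' @return An object of class `listener_model`.
#' @examples
#' listener_model(c("1000" = 15, "2000" = 20))
#' @export
listener_model <- function(true_threshold_hl, slope_db = 4,
                           guess_rate = 0.01, lapse_rate = 0.02,
                           latency_median_ms = 600,
                           latency_sigma_log = 0.35,
                           psychometric = c("normal", "logistic")) {
  if (is.data.frame(true_threshold_hl)) {
    thr <- stats::setNames(true_threshold_hl$threshold_hl,
                           as.integer(round(true_threshold_hl$frequency_hz)))
  } else {
    stopifnot(is.numeric(true_threshold_hl),
              !is.null(names(true_threshold_hl)))
    thr <- true_threshold_hl
    names(thr) <- as.integer(round(as.numeric(names(thr))))
  }
  stopifnot(slope_db >= 0, guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate < 1,
            guess_rate + lapse_rate < 1,
            latency_median_ms > 0, latency_sigma_log >= 0)
  structure(list(true_threshold_hl = thr, slope_db = slope_db,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 latency_median_ms = latency_median_ms,
                 latency_sigma_log = latency_sigma_log,
                 psychometric = match.arg(psychometric)),
            class = "listener_model")
}

#' Deterministic step observer
#'
#' Responds if and only if the level is at or above its true threshold,
#' with fixed latency: `slope_db = 0`, no guesses, no lapses. The
#' reference observer for staircase verification.
#'
#' @inheritParams listener_model
#' @param latency_ms Fixed press latency (default 600 ms).
#' @return A `listener_model`.
#' @export
deterministic_listener <- function(true_threshold_hl, latency_ms = 600) {
  listener_model(true_threshold_hl, slope_db = 0, guess_rate = 0,
                 lapse_rate = 0, latency_median_ms = latency_ms,
                 latency_sigma_log = 0)
}

#' Flat threshold map over a calibration table's frequencies
#'
#' @param level_hl The threshold (dB HL) applied at every frequency.
#' @param table A [calibration_table] supplying the frequencies.
#' @return A named numeric vector usable as `true_threshold_hl`.
#' @export
flat_thresholds <- function(level_hl, table) {
  stats::setNames(rep(level_hl, nrow(table)), table$frequency_hz)
}

#' @export
print.listener_model <- function(x, ...) {
  cat(sprintf(
    "<listener_model> %d frequencies, sigma %g dB, guess %g, lapse %g, latency %g ms (log-sd %g)\n",
    length(x$true_threshold_hl), x$slope_db, x$guess_rate, x$lapse_rate,
    x$latency_median_ms, x$latency_sigma_log))
  invisible(x)
}

#' Probability that a listener detects a level
#'
#' @param listener A [listener_model].
#' @param level_hl Presented level (dB HL).
#' @param frequency_hz Frequency (must be in the listener's threshold
#'   map).
#' @return Detection probability.
#' @export
detection_probability <- function(listener, level_hl, frequency_hz) {
  key <- as.character(as.integer(round(frequency_hz)))
  if (!key %in% names(listener$true_threshold_hl)) {
    stop("listener has no threshold at ", frequency_hz, " Hz",
         call. = FALSE)
  }
  t_hl <- listener$true_threshold_hl[[key]]
  if (listener$slope_db == 0) {
    return(as.numeric(level_hl >= t_hl))
  }
  z <- (level_hl - t_hl) / listener$slope_db
  core <- switch(listener$psychometric,
                 normal = stats::pnorm(z),
                 logistic = stats::plogis(z))
  listener$guess_rate +
    (1 - listener$guess_rate - listener$lapse_rate) * core
}

#' Simulate one button-press decision
#'
#' Draws a press from the psychometric function and a latency from the
#' log-normal latency distribution, using the current random generator
#' state. Whether a press is on time is decided by the procedure's
#' response window, not here.
#'
#' @inheritParams detection_probability
#' @return A list with `pressed` (logical) and `latency_ms` (`NA` when
#'   not pressed).
#' @export
respond <- function(listener, level_hl, frequency_hz) {
  p <- detection_probability(listener, level_hl, frequency_hz)
  pressed <- if (p >= 1) TRUE else if (p <= 0) FALSE else
    stats::runif(1) < p
  latency <- if (!pressed) {
    NA_real_
  } else if (listener$latency_sigma_log == 0) {
    listener$latency_median_ms
  } else {
    stats::rlnorm(1, meanlog = log(listener$latency_median_ms),
                  sdlog = listener$latency_sigma_log)
  }
  list(pressed = pressed, latency_ms = latency)
}
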