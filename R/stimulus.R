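#' Specify the tone-burst stimulus train
#'
#' The test signal is a train of gated pure-tone beeps: each beep has a
#' fade-in, a plateau, a fade-out, and a trailing silent pause. Defaults
#' give the audiometric five-beep train (50/200/50/100 ms), i.e. 2000 ms
#' of stimulation in total at 48 kHz.
#'
#' @param frequency_hz Tone frequency (must be below Nyquist at render
#'   time).
#' @param amplitude Peak amplitude of the scaled sine, in `[0, 1]`; see
#'   [amplification_to_amplitude()].
#' @param n_beeps Number of beeps (default 5).
#' @param fade_in_ms,plateau_ms,fade_out_ms,pause_ms Segment durations in
#'   ms (defaults 50, 200, 50, 100).
#' @param sample_rate_hz Sampling rate (default 48000).
#' @param fade_shape `"cosine"` for raised-cosine (Hann-flank) gates, the
#'   standard audiometric choice; `"linear"` for linear ramps.
#' @return An object of class `stimulus_spec`.
#' @examples
#' spec <- stimulus_spec(1000, amplitude = 0.1)
#' total_duration_ms(spec)  # 2000
#' @export
stimulus_spec <- function(frequency_hz, amplitude = 1, n_beeps = 5,
                          fade_in_ms = 50, plateau_ms = 200,
                          fade_out_ms = 50, pause_ms = 100,
                          sample_rate_hz = 48000,
                          fade_shape = c("cosine", "linear")) {
  stopifnot(frequency_hz > 0, amplitude >= 0, amplitude <= 1,
            n_beeps >= 0, fade_in_ms >= 0, plateau_ms >= 0,
            fade_out_ms >= 0, pause_ms >= 0, sample_rate_hz > 0)
  structure(list(frequency_hz = frequency_hz, amplitude = amplitude,
                 n_beeps = as.integer(n_beeps), fade_in_ms = fade_in_ms,
                 plateau_ms = plateau_ms, fade_out_ms = fade_out_ms,
                 pause_ms = pause_ms,
                 sample_rate_hz = as.integer(sample_rate_hz),
                 fade_shape = match.arg(fade_shape)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %g Hz, amplitude %.4g, %d beep(s) of %g/%g/%g ms + %g ms pause, %d Hz sampling (%s fades)\n",
    x$frequency_hz, x$amplitude, x$n_beeps, x$fade_in_ms, x$plateau_ms,
    x$fade_out_ms, x$pause_ms, x$sample_rate_hz, x$fade_shape))
  invisible(x)
}

#' Total stimulus duration
#'
#' `n_beeps * (fade_in + plateau + fade_out + pause)` in milliseconds.
#'
#' @param spec A [stimulus_spec].
#' @return Duration in ms.
#' @export
total_duration_ms <- function(spec) {
  spec$n_beeps *
    (spec$fade_in_ms + spec$plateau_ms + spec$fade_out_ms + spec$pause_ms)
}

fade_curve <- function(n, shape, rising) {
  if (n == 0) return(numeric(0))
  # ramp spanning (0, 1) over n samples; 0 at onset, reaching 1 at the
  # first plateau sample so adjacent samples never jump
  t <- seq_len(n) - 1
  env <- switch(shape,
                cosine = 0.5 * (1 - cos(pi * t / n)),
                linear = t / n)
  if (rising) env else rev(env)
}

#' Render a stimulus specification to a sampled waveform
#'
#' Each beep is a zero-phase sine at `frequency_hz`, scaled by `amplitude`
#' and gated by the fade-in / plateau / fade-out envelope, followed by an
#' exactly-zero pause; beeps are concatenated. Segment lengths are rounded
#' to the nearest sample.
#'
#' @param spec A [stimulus_spec].
#' @return An object of class `stimulus_waveform`: a list with `samples`
#'   (numeric in `[-1, 1]`), `sample_rate_hz` and `spec`.
#' @examples
#' wf <- render_stimulus(stimulus_spec(1000, amplitude = 0.5))
#' length(wf$samples)  # 96000
#' @export
render_stimulus <- function(spec) {
  sr <- spec$sample_rate_hz
  if (spec$frequency_hz >= sr / 2) {
    stop("frequency ", spec$frequency_hz, " Hz is at or above Nyquist (",
         sr / 2, " Hz)", call. = FALSE)
  }
  n_in <- round(spec$fade_in_ms * sr / 1000)
  n_pl <- round(spec$plateau_ms * sr / 1000)
  n_out <- round(spec$fade_out_ms * sr / 1000)
  n_pause <- round(spec$pause_ms * sr / 1000)
  env <- c(fade_curve(n_in, spec$fade_shape, rising = TRUE),
           rep(1, n_pl),
           fade_curve(n_out, spec$fade_shape, rising = FALSE),
           rep(0, n_pause))
  n_beep <- length(env)
  t <- (seq_len(n_beep) - 1) / sr
  beep <- spec$amplitude * sin(2 * pi * spec$frequency_hz * t) * env
  beep[env == 0] <- 0  # exact (unsigned) zeros in the pause
  samples <- rep(beep, spec$n_beeps)
  structure(list(samples = samples, sample_rate_hz = sr, spec = spec),
            class = "stimulus_waveform")
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf("<stimulus_waveform> %d samples at %d Hz (%.3f s), peak %.4g\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

# Envelope of one rendered beep, for tests and plotting.
beep_envelope <- function(spec) {
  sr <- spec$sample_rate_hz
  c(fade_curve(round(spec$fade_in_ms * sr / 1000), spec$fade_shape, TRUE),
    rep(1, round(spec$plateau_ms * sr / 1000)),
    fade_curve(round(spec$fade_out_ms * sr / 1000), spec$fade_shape, FALSE),
    rep(0, round(spec$pause_ms * sr / 1000)))
}

#' Render a calibrated stimulus at a given hearing level
#'
#' Convenience wrapper: converts `level_hl` at `frequency_hz` to digital
#' amplitude through the calibration table, then renders the beep train.
#'
#' @param table A [calibration_table].
#' @param frequency_hz Test frequency.
#' @param level_hl Hearing level in dB HL.
#' @param ... Passed to [stimulus_spec()].
#' @return A `stimulus_waveform`.
#' @export
render_calibrated <- function(table, frequency_hz, level_hl, ...) {
  amp_db <- hl_to_amplification(table, frequency_hz, level_hl)
  amp <- amplification_to_amplitude(amp_db,
                                    amp_max_db = attr(table, "amp_max_db"))
  render_stimulus(stimulus_spec(frequency_hz, amplitude = amp, ...))
}
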