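# Minimal mono RIFF/WAVE I/O. 16-bit integer PCM (format tag 1) and
# 32-bit IEEE float (format tag 3) are enough for audiometric stimuli.

#' Write a waveform to a WAV file
#'
#' Mono WAV export of a rendered stimulus (or any numeric sample vector in
#' `[-1, 1]`). `"float32"` stores samples losslessly; `"pcm16"` quantises
#' to 16-bit integers.
#'
#' @param waveform A `stimulus_waveform` from [render_stimulus()], or a
#'   numeric vector (then `sample_rate_hz` must be given).
#' @param path Output file path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @param sample_rate_hz Required when `waveform` is a bare numeric
#'   vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, format = c("float32", "pcm16"),
                      sample_rate_hz = NULL) {
  format <- match.arg(format)
  if (inherits(waveform, "stimulus_waveform")) {
    samples <- waveform$samples
    sr <- waveform$sample_rate_hz
  } else {
    stopifnot(is.numeric(waveform), !is.null(sample_rate_hz))
    samples <- waveform
    sr <- as.integer(sample_rate_hz)
  }
  if (any(abs(samples) > 1 + 1e-12)) {
    stop("samples exceed [-1, 1]; refusing to clip", call. = FALSE)
  }
  bits <- if (format == "float32") 32L else 16L
  fmt_tag <- if (format == "float32") 3L else 1L
  bytes_per <- bits %/% 8L
  data_bytes <- length(samples) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")   # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(samples, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmin(pmax(samples, -1), 1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads the formats [write_wav()] produces (mono 16-bit PCM or 32-bit
#' float).
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric) and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt_tag <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      stop("no data chunk found", call. = FALSE)
    }
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, "integer", size = 2, endian = "little")
      n_chan <- readBin(con, "integer", size = 2, endian = "little")
      sr <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
      if (n_chan != 1) stop("only mono WAV supported", call. = FALSE)
    } else if (id == "data") {
      if (is.null(fmt_tag)) stop("data chunk before fmt", call. = FALSE)
      samples <- if (fmt_tag == 3 && bits == 32) {
        readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
      } else if (fmt_tag == 1 && bits == 16) {
        readBin(con, "integer", n = sz / 2, size = 2,
                endian = "little") / 32767
      } else {
        stop("unsupported WAV format (tag ", fmt_tag, ", ", bits, " bit)",
             call. = FALSE)
      }
      return(list(samples = samples, sample_rate_hz = sr))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
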