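#' Construct an audio signal
#'
#' Lightweight container for a mono audio stream: a numeric sample vector in
#' `[-1, 1]` plus its sample rate. All audio entering the pitch tracker and
#' the speech pipeline is carried in this form.
#'
#' @param samples Numeric vector of sample amplitudes, finite, nominally in
#'   `[-1, 1]`.
#' @param rate Sample rate in Hz (default 16000, the rate the whole pipeline
#'   is parameterized for).
#' @return An object of class `audio_signal`: a list with elements `samples`
#'   and `rate`.
#' @export
#' @examples
#' sig <- audio_signal(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 16000)))
#' sig
audio_signal <- function(samples, rate = 16000) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) abort("`samples` must be non-empty.")
  if (!all(is.finite(samples))) abort("`samples` must be finite.")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    abort("`rate` must be a single positive number.")
  }
  structure(list(samples = samples, rate = rate), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %d samples, %.0f Hz, %.3f s, peak %.3f>\n",
    length(x$samples), x$rate, length(x$samples) / x$rate,
    max(abs(x$samples))
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

rms <- function(x) sqrt(mean(x^2))

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are quantized to the signed 16-bit grid on write, so a
#' write/read round trip differs from the original by at most half a
#' quantization step (1/32768).
#'
#' @param signal An [audio_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(pmax(signal$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(signal$rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Parses the RIFF chunk structure, rejects anything that is not mono 16-bit
#' integer PCM (naming the offending format), and scales samples to
#' `[-1, 1]`. A sample rate other than 16000 Hz is accepted with a warning;
#' [estimate_pitch()] rescales its analysis windows proportionally for such
#' signals.
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) abort("Not a WAV file: too short for a RIFF header.")
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) abort("Not a WAV file: missing RIFF tag.")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) abort("Not a WAV file: missing WAVE tag.")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    len <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      body <- readBin(con, raw(), len)
      fmt <- list(
        audio_format = readBin(body[1:2], integer(), 1, size = 2, endian = "little"),
        channels     = readBin(body[3:4], integer(), 1, size = 2, endian = "little"),
        rate         = readBin(body[5:8], integer(), 1, size = 4, endian = "little"),
        bits         = readBin(body[15:16], integer(), 1, size = 2, endian = "little")
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, raw(), len)
    } else {
      invisible(readBin(con, raw(), len + len %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("Malformed WAV: missing fmt or data chunk.")
  if (fmt$audio_format != 1L) {
    abort(sprintf("Unsupported WAV encoding: format code %d (only PCM is supported).",
                  fmt$audio_format))
  }
  if (fmt$channels != 1L) {
    abort(sprintf("Unsupported WAV layout: %d channels (only mono is supported).",
                  fmt$channels))
  }
  if (fmt$bits != 16L) {
    abort(sprintf("Unsupported WAV sample width: %d bits (only 16-bit PCM).", fmt$bits))
  }
  if (length(data_raw) == 0) abort("Empty WAV data chunk.")
  pcm <- readBin(data_raw, integer(), length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little")
  if (fmt$rate != 16000) {
    warn(sprintf("WAV sample rate is %d Hz, not 16000; analysis windows will be rescaled.",
                 fmt$rate))
  }
  audio_signal(pcm / 32767, rate = fmt$rate)
}
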