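#' Construct a mono waveform
#'
#' A `waveform` is the package's audio container: a finite real-valued sample
#' vector together with its sampling rate. All synthesis routines return
#' waveforms at 8 kHz, the rate at which the peripheral model is defined.
#'
#' @param samples Numeric vector of audio samples (arbitrary amplitude units).
#' @param rate_hz Sampling rate in samples/second (default 8000).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate_hz = 8000) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_param("`samples` must be a non-empty numeric vector")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop_param("waveform samples must all be finite")
  }
  check_scalar(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate_hz, duration(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wav A `waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(wav) {
  stopifnot(inherits(wav, "waveform"))
  length(wav$samples) / wav$rate_hz
}

# WAV (RIFF) I/O --------------------------------------------------------------
# Minimal mono writer/reader for 16-bit PCM and 32-bit IEEE float.

#' Write a waveform to a WAV file
#'
#' @param wav A `waveform`.
#' @param path Output file path.
#' @param format `"pcm16"` (samples scaled to peak) or `"float32"` (verbatim).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(wav, "waveform"))
  format <- match.arg(format)
  rate <- as.integer(round(wav$rate_hz))
  n <- length(wav$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    peak <- max(abs(wav$samples), 1e-12)
    data <- as.integer(round(wav$samples / peak * 32767))
    nbytes <- 2L * n
  } else {
    fmt_code <- 3L; bits <- 32L
    data <- wav$samples
    nbytes <- 4L * n
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(data, con, size = 2, endian = "little")
  } else {
    writeBin(data, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the 16-bit PCM and 32-bit float formats produced by [write_wav()].
#'
#' @param path Input file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_param("`%s` is not a RIFF/WAVE file", path)
  }
  fmt_code <- NULL; rate <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4) stop_param("no data chunk found")
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", size = 2, endian = "little")
      channels <- readBin(con, "integer", size = 2, endian = "little")
      rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop_param("data chunk precedes fmt chunk")
      if (channels != 1L) stop_param("only mono WAV is supported")
      if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "double", n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop_param("unsupported WAV format (code %d, %d bits)", fmt_code, bits)
      }
      return(waveform(samples, rate))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}

rms_normalize <- function(x) {
  r <- sqrt(mean(x^2))
  if (r < 1e-15) x else x / r
}
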