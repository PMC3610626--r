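# Simplified peripheral auditory model.
#
# A waveform is mapped to an "auditory spectrogram": a frames x channels
# energy matrix on a log-frequency (tonotopic) axis spanning six octaves
# (62.5-4000 Hz) with ten channels per octave, sampled every 5 ms. The
# stages are (per channel): constant-Q bandpass filtering -> half-wave
# rectification -> across-channel first difference (a lateral inhibitory
# network that sharpens frequency selectivity) -> half-wave rectification
# -> short-term integration over 5-ms windows.
#
# The bandpass magnitude responses are asymmetric on the log-frequency axis
# (shallow low-frequency side, steep high-frequency side), as in cochlear
# filters. The asymmetry matters: with the steep edge on the high side, the
# across-channel difference peaks at the channel whose center matches a tone,
# so the tonotopic axis keeps its place-code interpretation after the
# inhibition stage.

#' Design the constant-Q tonotopic filterbank
#'
#' Centers are `f_c = f_low * 2^(c / ch_per_octave)` for
#' `c = 0 ... n_octaves*ch_per_octave - 1`. Bandwidths scale with center
#' frequency (constant Q); the low- and high-side skirt widths are expressed
#' in octaves, with the defaults chosen so adjacent filters cross at -3 dB.
#'
#' @param n_octaves Number of octaves (default 6).
#' @param ch_per_octave Channels per octave (default 10).
#' @param f_low_hz Lowest center frequency (default 62.5 Hz).
#' @param rate_hz Sampling rate the bank is designed for (default 8000).
#' @param w_low_oct,w_high_oct Gaussian half-widths (octaves) of the low- and
#'   high-frequency skirts.
#' @return An object of class `filterbank` with `center_freqs_hz`.
#' @export
design_filterbank <- function(n_octaves = 6, ch_per_octave = 10,
                              f_low_hz = 62.5, rate_hz = 8000,
                              w_low_oct = 0.128, w_high_oct = 0.042) {
  check_scalar(n_octaves, "n_octaves", lower = 1)
  check_scalar(ch_per_octave, "ch_per_octave", lower = 1)
  check_scalar(f_low_hz, "f_low_hz", lower = 0, strict_lower = TRUE)
  if (f_low_hz * 2^n_octaves > rate_hz / 2) {
    stop_param("top octave (%.1f Hz) exceeds the Nyquist frequency %.1f Hz",
               f_low_hz * 2^n_octaves, rate_hz / 2)
  }
  n_ch <- as.integer(n_octaves * ch_per_octave)
  fc <- f_low_hz * 2^((0:(n_ch - 1)) / ch_per_octave)
  structure(list(center_freqs_hz = fc, rate_hz = rate_hz,
                 ch_per_octave = ch_per_octave,
                 w_low_oct = w_low_oct, w_high_oct = w_high_oct),
            class = "filterbank")
}

# magnitude response of channel c evaluated at frequencies f (Hz)
filter_magnitude <- function(fb, fc, f) {
  d <- rep(-Inf, length(f))
  pos <- f > 0
  d[pos] <- log2(f[pos] / fc)
  w <- ifelse(d <= 0, fb$w_low_oct, fb$w_high_oct)
  h <- exp(-(d / w)^2)
  h[!pos] <- 0
  h
}

#' Compute an auditory spectrogram
#'
#' Applies the simplified peripheral model to a waveform. All stages are
#' linear or positively homogeneous, so doubling the input amplitude doubles
#' the spectrogram.
#'
#' @param wav A [waveform()] at the filterbank's design rate.
#' @param fb A [design_filterbank()] object.
#' @param frame_ms Integration window in ms (default 5).
#' @param compression `"none"` (default) or `"cuberoot"` static amplitude
#'   compression applied to the final energies.
#' @return An `auditory_spectrogram`: a frames x channels matrix with
#'   attributes `center_freqs_hz` and `frame_ms`.
#' @export
compute_spectrogram <- function(wav, fb = design_filterbank(),
                                frame_ms = 5,
                                compression = c("none", "cuberoot")) {
  stopifnot(inherits(wav, "waveform"), inherits(fb, "filterbank"))
  compression <- match.arg(compression)
  if (length(wav$samples) == 0L) stop_param("empty waveform")
  if (abs(wav$rate_hz - fb$rate_hz) > 1e-9) {
    stop_param("waveform rate %g Hz does not match filterbank design rate %g",
               wav$rate_hz, fb$rate_hz)
  }
  n <- length(wav$samples)
  samples_per_frame <- round(frame_ms / 1000 * wav$rate_hz)
  n_frames <- floor(n / samples_per_frame)
  if (n_frames < 1L) stop_param("waveform shorter than one analysis frame")
  fc <- fb$center_freqs_hz
  n_ch <- length(fc)
  X <- stats::fft(wav$samples)
  freqs <- (0:(n - 1)) / n * wav$rate_hz
  folded <- pmin(freqs, wav$rate_hz - freqs)   # symmetric magnitude response
  n_used <- n_frames * samples_per_frame
  rect <- matrix(0, n_used, n_ch)
  for (c_idx in seq_len(n_ch)) {
    h <- filter_magnitude(fb, fc[c_idx], folded)
    y <- Re(stats::fft(X * h, inverse = TRUE)) / n
    rect[, c_idx] <- pmax(y[seq_len(n_used)], 0)
  }
  # lateral inhibition: first difference toward higher channels, rectified
  lin <- rect
  lin[, 2:n_ch] <- pmax(rect[, 2:n_ch] - rect[, 1:(n_ch - 1)], 0)
  # 5-ms integration: mean over non-overlapping windows
  dim(lin) <- c(samples_per_frame, n_frames, n_ch)
  values <- colMeans(lin)                      # n_frames x n_ch
  if (compression == "cuberoot") values <- values^(1 / 3)
  structure(values, class = c("auditory_spectrogram", "matrix", "array"),
            center_freqs_hz = fc, frame_ms = frame_ms)
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf("<auditory_spectrogram> %d frames x %d channels (%g ms frames, %g-%g Hz)\n",
              nrow(x), ncol(x), attr(x, "frame_ms"),
              min(attr(x, "center_freqs_hz")), max(attr(x, "center_freqs_hz"))))
  invisible(x)
}

#' Display an auditory spectrogram
#'
#' @param x An `auditory_spectrogram`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.auditory_spectrogram <- function(x, ...) {
  fm <- attr(x, "frame_ms")
  graphics::image(x = (seq_len(nrow(x)) - 0.5) * fm / 1000,
                  y = log2(attr(x, "center_freqs_hz")),
                  z = unclass(x), xlab = "time (s)",
                  ylab = "log2 frequency (Hz)", ...)
  invisible(x)
}
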