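# Synthetic stimulus generation.
#
# The learning experiments are driven by an ensemble of natural-sound-like
# stimuli: 3-s standardized segments of harmonic vocalizations (speech-like),
# moving-ripple mixtures (vocalization-like) and low-pass modulated noise
# (ambient-like), mixed 50/25/25 and randomly concatenated. The surrogates
# control the property that matters downstream: joint spectro-temporal
# modulation energy concentrated at low temporal rates and low spectral
# scales, as in natural sound ensembles.

TONOTOPIC_F_LOW <- 62.5
TONOTOPIC_CH_PER_OCT <- 10L
TONOTOPIC_N_OCT <- 6L

tonotopic_centers <- function() {
  TONOTOPIC_F_LOW * 2^((0:(TONOTOPIC_CH_PER_OCT * TONOTOPIC_N_OCT - 1)) /
                         TONOTOPIC_CH_PER_OCT)
}

#' Generate a moving ripple stimulus
#'
#' A moving ripple is a sum of log-spaced tone carriers whose amplitudes
#' follow a drifting sinusoidal spectro-temporal envelope with temporal
#' modulation `rate_hz` (Hz) and spectral modulation `scale_cpo`
#' (cycles/octave). Carriers sit exactly on the 60 tonotopic channel centers
#' (62.5-4000 Hz), so the ripple's modulation content falls on the analysis
#' grid of the front-end. `direction = "down"` drifts spectral peaks downward
#' in frequency over time.
#'
#' @param rate_hz Temporal modulation rate, `0 <= rate_hz < 100` Hz.
#' @param scale_cpo Spectral modulation scale, `0 <= scale_cpo <= 5` cyc/oct.
#' @param duration_s Duration in seconds.
#' @param direction `"down"` or `"up"` drift direction.
#' @param seed Integer seed for the carrier phases.
#' @param depth Modulation depth in (0, 1].
#' @return An RMS-normalized [waveform()] at 8 kHz.
#' @export
gen_moving_ripple <- function(rate_hz, scale_cpo, duration_s,
                              direction = c("down", "up"), seed = 1,
                              depth = 0.9) {
  direction <- match.arg(direction)
  check_scalar(rate_hz, "rate_hz", lower = 0, upper = 100, strict_upper = TRUE)
  check_scalar(scale_cpo, "scale_cpo", lower = 0, upper = 5)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(depth, "depth", lower = 0, upper = 1, strict_lower = TRUE)
  rate <- 8000
  t <- seq(0, by = 1 / rate, length.out = round(duration_s * rate))
  fc <- tonotopic_centers()
  oct <- log2(fc / TONOTOPIC_F_LOW)
  sgn <- if (direction == "down") 1 else -1
  phases <- with_local_seed(seed, stats::runif(length(fc), 0, 2 * pi))
  x <- numeric(length(t))
  for (c_idx in seq_along(fc)) {
    env <- 1 + depth * sin(2 * pi * (rate_hz * t + sgn * scale_cpo * oct[c_idx]))
    x <- x + env * cos(2 * pi * fc[c_idx] * t + phases[c_idx])
  }
  waveform(rms_normalize(x), rate)
}

#' Generate a harmonic vocalization surrogate
#'
#' A harmonic stack with a slowly varying pitch contour, a formant-shaped
#' spectral envelope (Gaussian bumps on the log-frequency axis), and optional
#' amplitude modulation -- a stand-in for speech syllables and animal calls.
#'
#' @param f0_contour Numeric vector of fundamental frequencies (Hz), linearly
#'   interpolated across the duration. All values in 62.5-4000 Hz.
#' @param formant_centers Formant center frequencies (Hz) in 62.5-4000 Hz.
#' @param am_rate_hz Amplitude modulation rate (Hz); 0 disables AM.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed for harmonic phases.
#' @param formant_bw_oct Formant bandwidth (octaves) of the Gaussian bumps.
#' @return An RMS-normalized [waveform()] at 8 kHz.
#' @export
gen_harmonic_call <- function(f0_contour, formant_centers, am_rate_hz = 0,
                              duration_s = 3, seed = 1, formant_bw_oct = 0.35) {
  if (length(f0_contour) == 0L || !is.numeric(f0_contour)) {
    stop_param("`f0_contour` must be a non-empty numeric vector")
  }
  if (any(f0_contour < 62.5) || any(f0_contour > 4000)) {
    stop_param("`f0_contour` must lie within 62.5-4000 Hz")
  }
  if (length(formant_centers) > 0 &&
      (any(formant_centers < 62.5) || any(formant_centers > 4000))) {
    stop_param("`formant_centers` must lie within 62.5-4000 Hz")
  }
  check_scalar(am_rate_hz, "am_rate_hz", lower = 0, upper = 100)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  rate <- 8000
  n <- round(duration_s * rate)
  if (n < 2L) stop_param("`duration_s` too short at 8 kHz")
  t <- seq(0, by = 1 / rate, length.out = n)
  f0 <- if (length(f0_contour) == 1L) rep(f0_contour, n) else {
    stats::approx(seq(0, 1, length.out = length(f0_contour)),
                  f0_contour, xout = seq(0, 1, length.out = n))$y
  }
  # formant envelope evaluated on log2 frequency
  formant_gain <- function(f) {
    g <- rep(0.05, length(f))
    for (fm in formant_centers) {
      g <- g + exp(-((log2(f / fm))^2) / (2 * formant_bw_oct^2))
    }
    g
  }
  n_harm <- max(1L, floor(4000 / max(f0)))
  phases <- with_local_seed(seed, stats::runif(n_harm, 0, 2 * pi))
  phase0 <- 2 * pi * cumsum(f0) / rate      # running fundamental phase
  x <- numeric(n)
  for (h in seq_len(n_harm)) {
    fh <- h * f0
    keep <- fh < 4000
    if (!any(keep)) next
    amp <- formant_gain(pmin(fh, 3999)) * keep
    x <- x + amp * cos(h * phase0 + phases[h])
  }
  if (am_rate_hz > 0) {
    x <- x * (1 + 0.9 * sin(2 * pi * am_rate_hz * t)) / 1.9
  }
  waveform(rms_normalize(x), rate)
}

#' Generate low-pass modulated noise
#'
#' An ambient-sound surrogate: a random spectro-temporal envelope is low-pass
#' filtered in 2D below the stated rate and scale cutoffs, then resynthesized
#' by amplitude-modulating narrowband carriers at the tonotopic channel
#' centers. Its average 2D modulation profile is therefore low-pass in both
#' rate and scale.
#'
#' @param rate_cutoff_hz Temporal modulation cutoff (Hz), positive.
#' @param scale_cutoff_cpo Spectral modulation cutoff (cyc/oct), positive.
#' @param duration_s Duration in seconds.
#' @param seed Integer seed.
#' @return An RMS-normalized [waveform()] at 8 kHz.
#' @export
gen_modulated_noise <- function(rate_cutoff_hz, scale_cutoff_cpo, duration_s,
                                seed = 1) {
  check_scalar(rate_cutoff_hz, "rate_cutoff_hz", lower = 0, strict_lower = TRUE)
  check_scalar(scale_cutoff_cpo, "scale_cutoff_cpo", lower = 0,
               strict_lower = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  rate <- 8000
  frame_s <- 0.005
  n <- round(duration_s * rate)
  n_frames <- max(4L, floor(duration_s / frame_s))
  n_ch <- TONOTOPIC_CH_PER_OCT * TONOTOPIC_N_OCT
  fc <- tonotopic_centers()
  seeds <- derive_seeds(seed, 2L)
  env <- with_local_seed(seeds[1], matrix(stats::rnorm(n_frames * n_ch),
                                          n_frames, n_ch))
  # 2D low-pass on the (rate, scale) modulation plane
  rate_ax <- fft_freqs(n_frames, 1 / frame_s)
  scale_ax <- fft_freqs(n_ch, TONOTOPIC_CH_PER_OCT)
  mask <- outer(abs(rate_ax) <= rate_cutoff_hz,
                abs(scale_ax) <= scale_cutoff_cpo)
  env <- Re(stats::fft(stats::fft(env) * mask, inverse = TRUE)) /
    (n_frames * n_ch)
  env <- env - min(env)                       # non-negative amplitude envelope
  # upsample each channel envelope to the audio rate, modulate carriers
  t_frames <- (seq_len(n_frames) - 0.5) * frame_s
  t <- seq(0, by = 1 / rate, length.out = n)
  phases <- with_local_seed(seeds[2], stats::runif(n_ch, 0, 2 * pi))
  x <- numeric(n)
  for (c_idx in seq_len(n_ch)) {
    e <- stats::approx(t_frames, env[, c_idx], xout = t, rule = 2)$y
    x <- x + e * cos(2 * pi * fc[c_idx] * t + phases[c_idx])
  }
  waveform(rms_normalize(x), rate)
}

# signed DFT frequency axis for length n at sampling rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k * fs / n
}

#' Stimulus ensemble recipe
#'
#' Describes how a synthetic natural-sound-like stimulus is assembled:
#' 3-s segments drawn from three surrogate classes (speech-like harmonic
#' calls, vocalization-like ripple mixtures, ambient-like modulated noise),
#' mixed in the stated fractions, each standardized to zero mean and unit
#' variance, raised-cosine tapered, and randomly concatenated.
#'
#' @param total_duration_s Total stimulus length in seconds (default 180).
#' @param segment_duration_s Segment length in seconds (default 3).
#' @param class_fractions Named fractions for `speech`, `vocalization`,
#'   `ambient`; non-negative, summing to 1 (default 0.5/0.25/0.25).
#' @param taper_ms Raised-cosine taper length per segment edge (default 50 ms).
#' @param seed Integer master seed.
#' @return An object of class `stimulus_recipe`.
#' @export
stimulus_recipe <- function(total_duration_s = 180, segment_duration_s = 3,
                            class_fractions = c(speech = 0.5,
                                                vocalization = 0.25,
                                                ambient = 0.25),
                            taper_ms = 50, seed = 1) {
  check_scalar(total_duration_s, "total_duration_s", lower = 0,
               strict_lower = TRUE)
  check_scalar(segment_duration_s, "segment_duration_s", lower = 0,
               strict_lower = TRUE)
  if (total_duration_s < segment_duration_s) {
    stop_param("`total_duration_s` must cover at least one segment")
  }
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop_param("`class_fractions` must be 3 non-negative values summing to 1")
  }
  if (is.null(names(class_fractions))) {
    names(class_fractions) <- c("speech", "vocalization", "ambient")
  }
  check_scalar(taper_ms, "taper_ms", lower = 0,
               upper = segment_duration_s * 500)
  structure(list(total_duration_s = total_duration_s,
                 segment_duration_s = segment_duration_s,
                 class_fractions = class_fractions,
                 taper_ms = taper_ms, seed = as.integer(seed)),
            class = "stimulus_recipe")
}

standardize_segment <- function(x) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-15) stop_param("degenerate (constant) segment cannot be standardized")
  x / s
}

raised_cosine_taper <- function(n, n_edge) {
  w <- rep(1, n)
  if (n_edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_edge) - 0.5) / n_edge))
    w[seq_len(n_edge)] <- ramp
    w[n - n_edge + seq_len(n_edge)] <- rev(ramp)
  }
  w
}

gen_segment <- function(class, dur, seed) {
  seeds <- derive_seeds(seed, 4L)
  params <- with_local_seed(seeds[1], switch(
    class,
    speech = list(
      f0 = exp(stats::runif(6, log(100), log(250))),
      formants = exp(stats::runif(3, log(300), log(3200))),
      am = stats::runif(1, 2, 8)),
    vocalization = list(
      n_rip = sample(2:3, 1),
      rates = exp(stats::runif(3, log(2), log(16))),
      scales = exp(stats::runif(3, log(0.25), log(1))),
      dirs = sample(c("down", "up"), 3, replace = TRUE)),
    ambient = list(
      rate_cut = stats::runif(1, 4, 12),
      scale_cut = stats::runif(1, 0.4, 1))))
  switch(class,
    speech = gen_harmonic_call(params$f0, params$formants, params$am, dur,
                               seed = seeds[2])$samples,
    vocalization = {
      x <- 0
      for (j in seq_len(params$n_rip)) {
        x <- x + gen_moving_ripple(params$rates[j], params$scales[j], dur,
                                   params$dirs[j], seed = seeds[1L + j])$samples
      }
      x
    },
    ambient = gen_modulated_noise(params$rate_cut, params$scale_cut, dur,
                                  seed = seeds[2])$samples)
}

#' Generate a stimulus ensemble from a recipe
#'
#' Builds the full training (or test) stimulus: per-class segments are
#' synthesized, standardized to zero mean and unit variance, raised-cosine
#' tapered, and concatenated in seeded random order. Class counts honor the
#' recipe fractions to within one segment (largest-remainder rounding).
#'
#' @param recipe A [stimulus_recipe()].
#' @return A [waveform()] with a `segments` attribute (data.frame of class
#'   labels and start times).
#' @export
gen_stimulus_ensemble <- function(recipe) {
  stopifnot(inherits(recipe, "stimulus_recipe"))
  dur <- recipe$segment_duration_s
  n_seg <- floor(recipe$total_duration_s / dur)
  if (n_seg < 1L) stop_param("total duration too short for one segment")
  # largest-remainder apportionment of segments to classes
  raw <- recipe$class_fractions * n_seg
  counts <- floor(raw)
  rem <- n_seg - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(names(counts), counts)
  seeds <- derive_seeds(recipe$seed, n_seg + 1L)
  order_idx <- with_local_seed(seeds[n_seg + 1L], sample.int(n_seg))
  classes <- classes[order_idx]
  rate <- 8000
  n_per <- round(dur * rate)
  n_edge <- round(recipe$taper_ms / 1000 * rate)
  taper <- raised_cosine_taper(n_per, n_edge)
  out <- numeric(n_seg * n_per)
  for (i in seq_len(n_seg)) {
    seg <- standardize_segment(gen_segment(classes[i], dur, seeds[i]))
    out[(i - 1) * n_per + seq_len(n_per)] <- seg * taper
  }
  wav <- waveform(out, rate)
  attr(wav, "segments") <- data.frame(class = classes,
                                      start_s = (seq_len(n_seg) - 1) * dur)
  wav
}

#' Generate latent-structured patches with a planted slow subspace
#'
#' A recovery fixture for the sustained-firing objective: columns are
#' `x_t = A s_t` with orthonormal mixing `A`, where the first `n_slow` sources
#' are temporally smooth (AR(1) with coefficient `sqrt(energy_autocorr)`, so
#' that the lag-1 autocorrelation of their *energies* equals
#' `energy_autocorr`) and the remaining `n_fast` sources are white. All
#' sources are standardized to unit variance.
#'
#' @param D Ambient dimension.
#' @param T_len Number of time steps (columns).
#' @param n_slow,n_fast Numbers of slow and fast sources, `n_slow + n_fast <= D`.
#' @param mixing_seed Integer seed for mixing and sources.
#' @param energy_autocorr Target lag-1 autocorrelation of slow-source energy
#'   (default 0.95).
#' @return A list with `X` (D x T matrix), `slow_basis` (D x n_slow, the true
#'   slow column space), `sources` (source matrix), and `mixing`.
#' @export
gen_slow_latent_patches <- function(D, T_len, n_slow, n_fast,
                                    mixing_seed = 1, energy_autocorr = 0.95) {
  if (!is.numeric(D) || D < 1) stop_param("`D` must be a positive integer")
  check_scalar(T_len, "T_len", lower = 2)
  check_scalar(energy_autocorr, "energy_autocorr", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (n_slow + n_fast > D) stop_param("n_slow + n_fast must not exceed D")
  n_src <- n_slow + n_fast
  if (n_src < 1L) stop_param("need at least one source")
  seeds <- derive_seeds(mixing_seed, 2L)
  # For a Gaussian AR(1) with coefficient phi, corr(s_t^2, s_{t-1}^2) = phi^2.
  phi <- sqrt(energy_autocorr)
  S <- with_local_seed(seeds[1], {
    S <- matrix(stats::rnorm(n_src * T_len), n_src, T_len)
    if (n_slow > 0) {
      for (i in seq_len(n_slow)) {
        s <- S[i, ]
        for (t in 2:T_len) s[t] <- phi * s[t - 1] + sqrt(1 - phi^2) * s[t]
        S[i, ] <- s
      }
    }
    S
  })
  S <- S / sqrt(rowMeans(S^2))                # unit variance sources
  A <- with_local_seed(seeds[2], qr.Q(qr(matrix(stats::rnorm(D * n_src), D))))
  A <- A[, seq_len(n_src), drop = FALSE]
  list(X = A %*% S,
       slow_basis = A[, seq_len(n_slow), drop = FALSE],
       sources = S, mixing = A)
}
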