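# Per-STRF characterization.
#
# Each STRF is a (frames x channels) spectro-temporal patch, 250 ms x 6
# octaves by default. Metrics:
#   * separability index (SPI): 1 - s1^2 / sum(s_k^2) over singular values;
#     0 for a rank-1 (time (x) frequency separable) pattern.
#   * modulation transfer function (MTF): magnitude of the 2D Fourier
#     transform of the +/-1 SD thresholded patch over signed temporal rate
#     (Hz) and non-negative spectral scale (cyc/oct).
#   * best rate / best scale: (|rate|, scale) at the MTF peak (DC excluded).
#   * rate and scale modulation profiles with upper 6-dB amplitude cutoffs.
#   * directionality index (DSI): normalized difference of MTF energy in the
#     (rate > 0, scale > 0) vs (rate < 0, scale > 0) quadrants; positive
#     values indicate a preference for downward-moving spectro-temporal
#     patterns under the patch orientation used here (frequency ascending
#     across columns, time across rows).
#   * compactness: isoperimetric quotient 4*pi*A/P^2 of the 10-dB isoline
#     ellipse of a least-squares Gaussian envelope fit, 1 for a circular
#     (spherical) excitatory region, -> 0 when elongated.

as_strf_patch <- function(x, patch_shape = NULL) {
  if (is.matrix(x)) return(unclass(x))
  if (is.numeric(x) && !is.null(patch_shape)) return(unstack_patch(x, patch_shape))
  stop_param("expected an STRF patch matrix")
}

#' Separability index of an STRF patch
#'
#' `SPI = 1 - sigma_1^2 / sum_k sigma_k^2` over the singular values of the
#' patch; 0 when the patch is exactly separable as a product of a temporal
#' and a spectral function (rank 1), approaching 1 for unstructured (noisy)
#' patterns. Invariant to transposition and scalar scaling.
#'
#' @param patch A (frames x channels) STRF matrix.
#' @return SPI in `[0, 1)`.
#' @export
separability_index <- function(patch) {
  patch <- as_strf_patch(patch)
  if (all(patch == 0)) stop_param("all-zero patch has undefined separability")
  d2 <- svd(patch, nu = 0, nv = 0)$d^2
  1 - d2[1] / sum(d2)
}

mtf_axes <- function(n_t, n_f, frame_ms = 5, ch_per_octave = 10) {
  rate <- sort(fft_freqs(n_t, 1000 / frame_ms))       # signed Hz, ascending
  n_half <- floor(n_f / 2)
  scale <- (0:n_half) * ch_per_octave / n_f           # cyc/oct, >= 0
  list(rate_hz = rate, scale_cpo = scale)
}

#' Modulation transfer function of an STRF patch
#'
#' Entries of the patch not exceeding `threshold_sd` standard deviations (in
#' absolute value, SD computed over the full patch) are zeroed, then the
#' magnitude of the 2D Fourier transform is taken. Because the patch is
#' real, the spectrum is conjugate-symmetric and only the `scale >= 0`
#' half-plane is kept, with the full signed rate axis. `threshold_sd = 0`
#' disables thresholding.
#'
#' @param patch A (frames x channels) STRF matrix.
#' @param threshold_sd Threshold in patch standard deviations (default 1).
#' @param frame_ms Temporal sampling of the patch (default 5 ms/frame).
#' @param ch_per_octave Spectral sampling (default 10 channels/octave).
#' @return An `mtf` object: `magnitude` (rate x scale matrix), `rate_hz`
#'   (signed, ascending), `scale_cpo` (non-negative).
#' @export
compute_mtf <- function(patch, threshold_sd = 1, frame_ms = 5,
                        ch_per_octave = 10) {
  patch <- as_strf_patch(patch)
  n_t <- nrow(patch); n_f <- ncol(patch)
  s <- stats::sd(patch)
  if (!is.finite(s) || s == 0) {
    warning("patch has zero variance; returning an all-zero MTF")
    thr <- patch * 0
  } else {
    thr <- patch
    thr[abs(thr) <= threshold_sd * s] <- 0
    if (all(thr == 0)) warning("thresholding removed the entire patch")
  }
  Fm <- abs(stats::fft(thr))
  ax <- mtf_axes(n_t, n_f, frame_ms, ch_per_octave)
  # reorder rows to ascending signed rate; keep scale >= 0 half-plane
  raw_rate <- fft_freqs(n_t, 1000 / frame_ms)
  mag <- Fm[order(raw_rate), seq_len(floor(n_f / 2) + 1L), drop = FALSE]
  structure(list(magnitude = mag, rate_hz = ax$rate_hz,
                 scale_cpo = ax$scale_cpo,
                 thresholded_energy = sum(thr^2), n_cells = n_t * n_f),
            class = "mtf")
}

#' @export
print.mtf <- function(x, ...) {
  cat(sprintf("<mtf> %d rate x %d scale bins (rate %g..%g Hz, scale 0..%g cyc/oct)\n",
              nrow(x$magnitude), ncol(x$magnitude), min(x$rate_hz),
              max(x$rate_hz), max(x$scale_cpo)))
  invisible(x)
}

#' Display an MTF (or ensemble MTF)
#'
#' @param x An `mtf`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.mtf <- function(x, ...) {
  graphics::image(x = x$rate_hz, y = x$scale_cpo, z = x$magnitude,
                  xlab = "rate (Hz)", ylab = "scale (cyc/oct)", ...)
  invisible(x)
}

#' Best rate and best scale of an MTF
#'
#' The `(|rate|, scale)` coordinates of the global MTF magnitude maximum.
#' The DC bin (rate = 0, scale = 0) is excluded from the search; ties are
#' broken toward smaller `|rate|`, then smaller scale.
#'
#' @param mtf An [compute_mtf()] object.
#' @return Named vector `c(br_hz, bs_cpo)`; `NA`s if the MTF is all zero.
#' @export
best_rate_scale <- function(mtf) {
  stopifnot(inherits(mtf, "mtf"))
  mag <- mtf$magnitude
  dc_row <- which(mtf$rate_hz == 0)
  mag[dc_row, 1] <- -Inf                       # exclude DC
  if (all(mag <= 0)) {
    warning("all-zero MTF; best rate/scale undefined")
    return(c(br_hz = NA_real_, bs_cpo = NA_real_))
  }
  peak <- max(mag)
  idx <- which(mag >= peak - .Machine$double.eps * peak, arr.ind = TRUE)
  cand <- data.frame(abs_rate = abs(mtf$rate_hz[idx[, 1]]),
                     scale = mtf$scale_cpo[idx[, 2]])
  best <- order(cand$abs_rate, cand$scale)[1]
  c(br_hz = cand$abs_rate[best], bs_cpo = cand$scale[best])
}

fold_rate <- function(mtf) {
  # merge +/- rate rows by summation; DC and (even-length) Nyquist unpaired
  rates <- mtf$rate_hz
  abs_rates <- sort(unique(abs(rates)))
  folded <- matrix(0, length(abs_rates), ncol(mtf$magnitude))
  for (i in seq_along(abs_rates)) {
    folded[i, ] <- colSums(mtf$magnitude[abs(rates) == abs_rates[i], ,
                                         drop = FALSE])
  }
  list(abs_rate_hz = abs_rates, magnitude = folded)
}

profile_cutoff <- function(axis, profile, drop = 10^(-6 / 20)) {
  peak_idx <- which.max(profile)
  if (peak_idx == length(profile) ||
      all(profile[(peak_idx + 1):length(profile)] > drop)) {
    warning("profile never falls below the cutoff level above its peak; ",
            "returning the axis maximum")
    return(axis[length(axis)])
  }
  # highest crossing of the cutoff level above the peak
  below <- which(profile <= drop & seq_along(profile) > peak_idx)
  j <- below[1]
  x0 <- axis[j - 1]; x1 <- axis[j]
  y0 <- profile[j - 1]; y1 <- profile[j]
  x0 + (y0 - drop) / (y0 - y1) * (x1 - x0)
}

#' Rate and scale modulation profiles with 6-dB cutoffs
#'
#' The MTF is folded along the rate axis (merging +/- rates); the rate
#' profile sums the folded MTF over scale and the scale profile sums over
#' |rate|. Each profile is normalized to peak 1 and summarized by its upper
#' 6-dB cutoff: the highest frequency above the peak at which the amplitude
#' profile crosses `10^(-6/20) ~ 0.501`, linearly interpolated between bins.
#'
#' @param mtf An [compute_mtf()] object.
#' @return A list with `rate` and `scale` data.frames (`axis`, `profile`)
#'   and scalars `rate_cutoff6dB_hz`, `scale_cutoff6dB_cpo`.
#' @export
modulation_profiles <- function(mtf) {
  stopifnot(inherits(mtf, "mtf"))
  if (all(mtf$magnitude == 0)) stop_param("all-zero MTF has no profiles")
  folded <- fold_rate(mtf)
  rate_prof <- rowSums(folded$magnitude)
  scale_prof <- colSums(folded$magnitude)
  rate_prof <- rate_prof / max(rate_prof)
  scale_prof <- scale_prof / max(scale_prof)
  list(rate = data.frame(axis = folded$abs_rate_hz, profile = rate_prof),
       scale = data.frame(axis = mtf$scale_cpo, profile = scale_prof),
       rate_cutoff6dB_hz = profile_cutoff(folded$abs_rate_hz, rate_prof),
       scale_cutoff6dB_cpo = profile_cutoff(mtf$scale_cpo, scale_prof))
}

#' Directionality index of an MTF
#'
#' `DSI = (R1 - R2) / (R1 + R2)` with `R1` the energy (squared magnitude) in
#' the (rate > 0, scale > 0) quadrant and `R2` in (rate < 0, scale > 0).
#' Positive values indicate a preference for downward frequency sweeps,
#' negative for upward. The unpaired rate Nyquist bin is excluded so that
#' separable patches give exactly 0.
#'
#' @param mtf An [compute_mtf()] object with a signed rate axis.
#' @return DSI in `[-1, 1]`, or `NA` if both quadrants are empty.
#' @export
directionality_index <- function(mtf) {
  stopifnot(inherits(mtf, "mtf"))
  rates <- mtf$rate_hz
  paired <- abs(rates) %in% abs(rates[rates > 0])   # drop unpaired Nyquist row
  pos_scale <- mtf$scale_cpo > 0
  E <- mtf$magnitude^2
  R1 <- sum(E[rates > 0 & paired, pos_scale])
  R2 <- sum(E[rates < 0 & paired, pos_scale])
  if (R1 + R2 == 0) {
    warning("no off-axis modulation energy; DSI undefined")
    return(NA_real_)
  }
  (R1 - R2) / (R1 + R2)
}

# 2D Gaussian envelope model used by compactness(): amplitude A and quadratic
# form Q (SPD, Cholesky-parameterized) around center (t0, f0), evaluated on
# the patch grid in bin units.
gauss_envelope <- function(par, tt, ff) {
  l11 <- exp(par[4]); l21 <- par[5]; l22 <- exp(par[6])
  dt <- tt - par[2]; df <- ff - par[3]
  u <- l11 * dt
  v <- l21 * dt + l22 * df
  exp(par[1]) * exp(-(u^2 + v^2))
}

#' Compactness (isoperimetric quotient) of an STRF patch
#'
#' Fits a single 2D Gaussian envelope to the absolute value of the
#' thresholded patch by least squares (moment initialization followed by
#' quasi-Newton refinement), extracts the isoline 10 dB below the envelope
#' maximum -- an ellipse in the spectro-temporal plane (bin units) -- and
#' returns `q = 4*pi*A / P^2` with the ellipse area `A` and its perimeter `P`
#' (Ramanujan approximation). `q = 1` for a circular region.
#'
#' @param patch A (frames x channels) STRF matrix.
#' @param threshold_sd Threshold in patch SDs applied before fitting.
#' @param drop_db Isoline level below the envelope maximum (default 10 dB).
#' @return Compactness in `(0, 1]`, or `NA` if the fit is degenerate.
#' @export
compactness <- function(patch, threshold_sd = 1, drop_db = 10) {
  patch <- as_strf_patch(patch)
  s <- stats::sd(patch)
  target <- abs(patch)
  if (is.finite(s) && s > 0) target[target <= threshold_sd * s] <- 0
  if (all(target == 0)) {
    warning("no supra-threshold energy; compactness undefined")
    return(NA_real_)
  }
  n_t <- nrow(target); n_f <- ncol(target)
  tt <- matrix(seq_len(n_t), n_t, n_f)
  ff <- matrix(seq_len(n_f), n_t, n_f, byrow = TRUE)
  w <- target / sum(target)
  t0 <- sum(w * tt); f0 <- sum(w * ff)
  vt <- max(sum(w * (tt - t0)^2), 0.25)
  vf <- max(sum(w * (ff - f0)^2), 0.25)
  cf <- sum(w * (tt - t0) * (ff - f0))
  # moment init: Q = Sigma^(-1)/2 so that envelope ~ exp(-x' Q x)
  Sig <- matrix(c(vt, cf, cf, vf), 2)
  Qm <- tryCatch(solve(Sig) / 2, error = function(e) NULL)
  if (is.null(Qm) || any(!is.finite(Qm)) || det(Qm) <= 0) {
    Qm <- diag(c(1 / (2 * vt), 1 / (2 * vf)))
  }
  L <- tryCatch(t(chol(Qm)), error = function(e) diag(sqrt(diag(Qm))))
  par0 <- c(log(max(target)), t0, f0, log(L[1, 1]), L[2, 1], log(L[2, 2]))
  sse <- function(par) {
    r <- gauss_envelope(par, tt, ff) - target
    sum(r^2)
  }
  fit <- tryCatch(stats::optim(par0, sse, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$par))) {
    warning("Gaussian envelope fit failed; compactness undefined")
    return(NA_real_)
  }
  l11 <- exp(fit$par[4]); l21 <- fit$par[5]; l22 <- exp(fit$par[6])
  L <- matrix(c(l11, l21, 0, l22), 2)
  Q <- L %*% t(L)
  if (any(!is.finite(Q))) {
    warning("degenerate envelope; compactness undefined")
    return(NA_real_)
  }
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || any(!is.finite(ev))) {
    warning("degenerate envelope; compactness undefined")
    return(NA_real_)
  }
  q0 <- log(10^(drop_db / 20))            # exp(-q0) amplitude drop
  semi <- sqrt(q0 / ev)                   # ellipse semi-axes (bin units)
  a <- semi[1]; b <- semi[2]
  area <- pi * a * b
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * area / perim^2
}

#' Characterize every STRF in an ensemble
#'
#' Runs the per-filter metrics over all STRFs of an ensemble (or a list of
#' patch matrices) and returns one row per STRF.
#'
#' @param x An `strf_ensemble` with raw-space STRFs, a D x K filter matrix,
#'   or a list of patch matrices.
#' @param patch_shape `c(frames, channels)` used to unstack filter columns.
#' @param threshold_sd MTF/compactness threshold in patch SDs.
#' @return A data.frame with columns `id`, `spi`, `br_hz`, `bs_cpo`, `dsi`,
#'   `compactness`, `rate_cutoff6dB_hz`, `scale_cutoff6dB_cpo`.
#' @export
strf_metrics <- function(x, patch_shape = c(50L, 60L), threshold_sd = 1) {
  patches <- strf_patch_list(x, patch_shape)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    mtf <- suppressWarnings(compute_mtf(p, threshold_sd = threshold_sd))
    brbs <- suppressWarnings(best_rate_scale(mtf))
    prof <- if (all(mtf$magnitude == 0)) {
      list(rate_cutoff6dB_hz = NA_real_, scale_cutoff6dB_cpo = NA_real_)
    } else suppressWarnings(modulation_profiles(mtf))
    data.frame(id = i,
               spi = separability_index(p),
               br_hz = brbs[["br_hz"]], bs_cpo = brbs[["bs_cpo"]],
               dsi = suppressWarnings(directionality_index(mtf)),
               compactness = suppressWarnings(compactness(p, threshold_sd)),
               rate_cutoff6dB_hz = prof$rate_cutoff6dB_hz,
               scale_cutoff6dB_cpo = prof$scale_cutoff6dB_cpo)
  })
  do.call(rbind, rows)
}

strf_patch_list <- function(x, patch_shape = c(50L, 60L)) {
  if (inherits(x, "strf_ensemble")) {
    if (is.null(x$strfs)) {
      stop_param("ensemble carries no raw-space STRFs; refit with a whitening model")
    }
    ps <- if (!is.null(x$patch_shape)) x$patch_shape else patch_shape
    return(lapply(seq_len(ncol(x$strfs)),
                  function(k) unstack_patch(x$strfs[, k], ps)))
  }
  if (is.list(x)) return(lapply(x, as_strf_patch))
  if (is.matrix(x)) {
    return(lapply(seq_len(ncol(x)), function(k) unstack_patch(x[, k], patch_shape)))
  }
  stop_param("cannot interpret `x` as a set of STRFs")
}
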