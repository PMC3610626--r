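# Population-level analyses: ensemble MTFs and contours, activation
# persistence, average population response histograms, the stimulus's own
# average 2D modulation profile, and symmetric-KL comparison of ensembles
# via nearest-neighbor similarity distributions.

#' Ensemble modulation transfer function
#'
#' Averages the per-STRF MTF magnitudes of an ensemble and extracts isoline
#' contours at a stated fraction of the eMTF maximum (the level used for
#' overlaying ensemble coverage on stimulus modulation profiles).
#'
#' @param x An `strf_ensemble`, filter matrix, or list of patches (see
#'   [strf_metrics()]).
#' @param threshold_sd Per-STRF threshold in patch SDs (default 1).
#' @param contour_level Contour level as a fraction of the eMTF maximum
#'   (default 0.65).
#' @param patch_shape `c(frames, channels)` for unstacking filter columns.
#' @return An `mtf` object with an added `contours` field (list of polylines
#'   with `rate_hz`/`scale_cpo` coordinates).
#' @export
ensemble_mtf <- function(x, threshold_sd = 1, contour_level = 0.65,
                         patch_shape = c(50L, 60L)) {
  patches <- strf_patch_list(x, patch_shape)
  if (length(patches) == 0L) stop_param("empty ensemble")
  check_scalar(contour_level, "contour_level", lower = 0, upper = 1,
               strict_lower = TRUE)
  acc <- NULL
  ax <- NULL
  for (p in patches) {
    m <- suppressWarnings(compute_mtf(p, threshold_sd = threshold_sd))
    if (is.null(acc)) {
      acc <- m$magnitude
      ax <- m
    } else {
      acc <- acc + m$magnitude
    }
  }
  emtf <- structure(list(magnitude = acc / length(patches),
                         rate_hz = ax$rate_hz, scale_cpo = ax$scale_cpo),
                    class = "mtf")
  lvl <- contour_level * max(emtf$magnitude)
  emtf$contours <- if (max(emtf$magnitude) <= 0) {
    list()
  } else if (contour_level >= 1) {
    # degenerate contour: the peak point(s)
    idx <- which(emtf$magnitude >= lvl, arr.ind = TRUE)
    lapply(seq_len(nrow(idx)), function(i) {
      list(rate_hz = emtf$rate_hz[idx[i, 1]],
           scale_cpo = emtf$scale_cpo[idx[i, 2]])
    })
  } else {
    cl <- grDevices::contourLines(x = emtf$rate_hz, y = emtf$scale_cpo,
                                  z = emtf$magnitude, levels = lvl)
    lapply(cl, function(li) list(rate_hz = li$x, scale_cpo = li$y))
  }
  emtf$contour_level <- contour_level
  emtf
}

#' Activation times and the persistent subset of an ensemble
#'
#' A neuron is "active" while the magnitude of its response exceeds one
#' temporal standard deviation (its own). Activation events are maximal
#' supra-threshold runs; their durations (run length x frame step) are
#' summarized per neuron by the median and interquartile range. Neurons are
#' sorted by descending median activation and the top 10% form the
#' "persistent" subset.
#'
#' @param Y K x T response matrix.
#' @param threshold_sd Threshold in per-neuron temporal SDs (default 1).
#' @param mode `"magnitude"` thresholds `|y|` (default); `"signed"`
#'   thresholds `y` itself.
#' @param frame_ms Frame step in ms (default 5).
#' @param persistent_fraction Fraction of neurons in the persistent subset.
#' @return An `activation_summary`: a data.frame (`neuron`, `median_ms`,
#'   `iqr_ms`, `n_events`) sorted by descending median, with attribute
#'   `persistent` (neuron indices of the top fraction).
#' @export
activation_times <- function(Y, threshold_sd = 1,
                             mode = c("magnitude", "signed"), frame_ms = 5,
                             persistent_fraction = 0.1) {
  mode <- match.arg(mode)
  check_matrix(Y, "Y")
  if (ncol(Y) < 2L) stop_param("need at least two time points")
  K <- nrow(Y)
  stats_per <- lapply(seq_len(K), function(i) {
    y <- Y[i, ]
    thr <- threshold_sd * stats::sd(y)
    above <- if (mode == "magnitude") abs(y) > thr else y > thr
    r <- rle(above)
    dur <- r$lengths[r$values] * frame_ms
    if (length(dur) == 0L) {
      c(median_ms = 0, iqr_ms = 0, n_events = 0)
    } else {
      c(median_ms = stats::median(dur), iqr_ms = stats::IQR(dur),
        n_events = length(dur))
    }
  })
  tab <- data.frame(neuron = seq_len(K), do.call(rbind, stats_per))
  tab <- tab[order(-tab$median_ms, tab$neuron), ]
  rownames(tab) <- NULL
  n_top <- ceiling(persistent_fraction * K)
  structure(tab, class = c("activation_summary", "data.frame"),
            persistent = tab$neuron[seq_len(n_top)])
}

#' Average population response histogram
#'
#' Histograms the instantaneous population response `{y_i(t)}` at each time
#' over fixed bin edges and averages the histograms across time (masses sum
#' to 1). Values beyond the outermost edges are counted in the edge bins.
#' `include_mask` restricts the population to a subset of neurons (e.g., the
#' non-noisy classes from clustering); `rescale_unit_variance` normalizes
#' each included response to unit temporal variance first, the footing on
#' which comparison ensembles (principal components, random filters) are put.
#'
#' @param Y K x T response matrix, K >= 2.
#' @param breaks Bin edges (default 101 uniform bins on `[-6, 6]`).
#' @param include_mask Logical or integer neuron subset (default all).
#' @param rescale_unit_variance Rescale rows to unit variance first?
#' @return A data.frame with `mid` (bin centers) and `mass` (averaged
#'   histogram masses summing to 1).
#' @export
population_response_histogram <- function(Y,
                                          breaks = seq(-6, 6, length.out = 102),
                                          include_mask = NULL,
                                          rescale_unit_variance = FALSE) {
  check_matrix(Y, "Y")
  if (!is.null(include_mask)) {
    Y <- Y[include_mask, , drop = FALSE]
  }
  if (nrow(Y) < 2L) stop_param("need at least two neurons after masking")
  if (rescale_unit_variance) {
    sds <- apply(Y, 1L, stats::sd)
    if (any(sds < 1e-12)) stop_param("cannot rescale constant responses")
    Y <- Y / sds
  }
  # equal population size at every t: the time-average of per-time histograms
  # equals the pooled histogram
  vals <- pmin(pmax(as.numeric(Y), breaks[1]), breaks[length(breaks)])
  counts <- graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
  data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mass = counts / length(vals))
}

#' Kurtosis of a binned response distribution
#'
#' Raw (non-excess) kurtosis computed from histogram bin centers and masses;
#' used to quantify how peaked/long-tailed an averaged population response
#' histogram is (3 for a Gaussian).
#'
#' @param hist A data.frame from [population_response_histogram()].
#' @return Scalar kurtosis.
#' @export
histogram_kurtosis <- function(hist) {
  m <- sum(hist$mid * hist$mass)
  v <- sum((hist$mid - m)^2 * hist$mass)
  sum((hist$mid - m)^4 * hist$mass) / v^2
}

#' Average 2D modulation profile of a stimulus spectrogram
#'
#' Averages the magnitude of the 2D Fourier transform over non-overlapping
#' 250-ms (50-frame) patches of the auditory spectrogram, on the same
#' (rate, scale) axes as STRF MTFs. This is the stimulus-side quantity the
#' ensemble MTFs are compared against.
#'
#' @param spec An `auditory_spectrogram`.
#' @param win_frames Patch length in frames (default 50).
#' @return An `mtf` object.
#' @export
stimulus_modulation_profile <- function(spec, win_frames = 50L) {
  stopifnot(inherits(spec, "auditory_spectrogram"))
  n_frames <- nrow(spec)
  n_ch <- ncol(spec)
  n_patches <- floor(n_frames / win_frames)
  if (n_patches < 1L) stop_param("spectrogram shorter than one %d-frame patch",
                                 win_frames)
  frame_ms <- attr(spec, "frame_ms")
  acc <- matrix(0, win_frames, floor(n_ch / 2) + 1L)
  raw_rate <- fft_freqs(win_frames, 1000 / frame_ms)
  ord <- order(raw_rate)
  for (p in seq_len(n_patches)) {
    block <- unclass(spec)[(p - 1L) * win_frames + seq_len(win_frames), ,
                           drop = FALSE]
    Fm <- abs(stats::fft(block))
    acc <- acc + Fm[ord, seq_len(floor(n_ch / 2) + 1L), drop = FALSE]
  }
  ax <- mtf_axes(win_frames, n_ch, frame_ms)
  structure(list(magnitude = acc / n_patches, rate_hz = ax$rate_hz,
                 scale_cpo = ax$scale_cpo, n_patches = n_patches),
            class = "mtf")
}

nn_similarities <- function(patches, reference, exclude_self = FALSE) {
  vapply(seq_along(patches), function(i) {
    sims <- vapply(seq_along(reference), function(j) {
      if (exclude_self && i == j) return(-Inf)
      strf_similarity(patches[[i]], reference[[j]])
    }, numeric(1))
    max(sims)
  }, numeric(1))
}

#' Symmetric KL divergence between nearest-neighbor similarity distributions
#'
#' For each STRF of ensembles `a` and `b`, its nearest-neighbor similarity is
#' the maximum [strf_similarity()] to the reference set (self-matches are
#' excluded when an ensemble is compared against itself). The two NN
#' similarity distributions are histogrammed on shared bins with additive
#' smoothing and compared by `KL(p||q) + KL(q||p)` in nats.
#'
#' @param ensemble_a,ensemble_b Ensembles (see [strf_metrics()] for accepted
#'   forms), each with at least 2 STRFs.
#' @param reference Reference set; defaults to `ensemble_b`.
#' @param bins Number of shared histogram bins (default 20).
#' @param smooth Additive smoothing mass per bin (default 1e-6).
#' @param patch_shape `c(frames, channels)` for unstacking filter columns.
#' @return Non-negative scalar divergence (nats).
#' @export
nn_similarity_kl <- function(ensemble_a, ensemble_b, reference = NULL,
                             bins = 20, smooth = 1e-6,
                             patch_shape = c(50L, 60L)) {
  pa <- strf_patch_list(ensemble_a, patch_shape)
  pb <- strf_patch_list(ensemble_b, patch_shape)
  if (length(pa) < 2L || length(pb) < 2L) {
    stop_param("each ensemble needs at least 2 STRFs")
  }
  pr <- if (is.null(reference)) pb else strf_patch_list(reference, patch_shape)
  nn_a <- nn_similarities(pa, pr, exclude_self = identical(pa, pr))
  nn_b <- nn_similarities(pb, pr, exclude_self = identical(pb, pr))
  lo <- min(nn_a, nn_b); hi <- max(nn_a, nn_b)
  if (hi - lo < 1e-12) {
    warning("degenerate single-bin NN similarity distributions; divergence 0")
    return(0)
  }
  edges <- seq(lo, hi, length.out = bins + 1L)
  p <- graphics::hist(nn_a, breaks = edges, plot = FALSE)$counts
  q <- graphics::hist(nn_b, breaks = edges, plot = FALSE)$counts
  symmetric_kl(p, q, smooth)
}

# symmetric KL divergence (nats) between two histograms given as counts or
# masses on shared bins, with additive smoothing
symmetric_kl <- function(p, q, smooth = 1e-6) {
  p <- p / sum(p) + smooth; p <- p / sum(p)
  q <- q / sum(q) + smooth; q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}
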