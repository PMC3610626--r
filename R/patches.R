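# Spectro-temporal patch extraction and whitening.
#
# STRFs are learned on 250-ms spectro-temporal patches of the auditory
# spectrogram, extracted once every 5 ms and stacked columnwise into vectors
# of dimension D = 50 frames x 60 channels = 3000. Each patch is mean-removed
# and scaled to unit norm, then reduced by PCA to the leading components
# capturing 95% of the variance and whitened. The unit-variance/decorrelation
# constraint on ensemble responses (response constraints) then reduces to
# orthonormality of the filter matrix in whitened coordinates: for any B with
# orthonormal columns, the raw-space filters H = E Lambda^(-1/2) B satisfy
# cov(H' X) = I on the fitting data.

#' Extract spectro-temporal patches from an auditory spectrogram
#'
#' Slides a `win_ms` window (default 250 ms = 50 frames) along the
#' spectrogram in steps of one frame (5 ms) and stacks each windowed block
#' columnwise into a patch vector. Stacking is temporal-major: the first
#' frame's 60 channel values occupy the first 60 entries, so element
#' (frame f, channel c), zero-based, lands at index `f*60 + c`.
#'
#' @param spec An `auditory_spectrogram` from [compute_spectrogram()].
#' @param win_ms Patch window length in ms (default 250).
#' @param hop_ms Hop between patches in ms; must equal the frame step.
#' @return A `patch_matrix`: D x T numeric matrix with attributes
#'   `patch_shape = c(frames, channels)`, `hop_ms`, and `preprocessed = FALSE`.
#' @export
extract_patches <- function(spec, win_ms = 250, hop_ms = 5) {
  stopifnot(inherits(spec, "auditory_spectrogram"))
  frame_ms <- attr(spec, "frame_ms")
  if (abs(hop_ms - frame_ms) > 1e-9) {
    stop_param("`hop_ms` (%g) must equal the spectrogram frame step (%g ms)",
               hop_ms, frame_ms)
  }
  frames_per_patch <- as.integer(round(win_ms / frame_ms))
  n_frames <- nrow(spec)
  n_ch <- ncol(spec)
  if (n_frames < frames_per_patch) {
    stop_param("spectrogram has %d frames; need at least %d for one patch",
               n_frames, frames_per_patch)
  }
  T_len <- n_frames - frames_per_patch + 1L
  D <- frames_per_patch * n_ch
  X <- matrix(0, D, T_len)
  vals <- unclass(spec)
  for (f in seq_len(frames_per_patch)) {
    X[(f - 1L) * n_ch + seq_len(n_ch), ] <-
      t(vals[f:(f + T_len - 1L), , drop = FALSE])
  }
  new_patch_matrix(X, patch_shape = c(frames_per_patch, n_ch),
                   hop_ms = hop_ms, preprocessed = FALSE)
}

new_patch_matrix <- function(X, patch_shape, hop_ms, preprocessed) {
  structure(X, class = c("patch_matrix", "matrix", "array"),
            patch_shape = as.integer(patch_shape), hop_ms = hop_ms,
            preprocessed = preprocessed)
}

#' @export
print.patch_matrix <- function(x, ...) {
  ps <- attr(x, "patch_shape")
  cat(sprintf("<patch_matrix> D = %d (%d frames x %d channels), T = %d%s\n",
              nrow(x), ps[1], ps[2], ncol(x),
              if (isTRUE(attr(x, "preprocessed"))) ", preprocessed" else ""))
  invisible(x)
}

#' Reshape a stacked patch vector back to a (frames x channels) matrix
#'
#' Inverse of the columnwise stacking used by [extract_patches()]; useful for
#' viewing learned STRFs as spectro-temporal patterns.
#'
#' @param x A length-D patch (or filter) vector.
#' @param patch_shape Integer vector `c(frames, channels)`.
#' @return A frames x channels matrix.
#' @export
unstack_patch <- function(x, patch_shape = c(50L, 60L)) {
  if (length(x) != prod(patch_shape)) {
    stop_param("vector length %d does not match patch shape %d x %d",
               length(x), patch_shape[1], patch_shape[2])
  }
  # temporal-major stacking: channels vary fastest
  t(matrix(as.numeric(x), patch_shape[2], patch_shape[1]))
}

#' Mean-remove and unit-normalize patch vectors
#'
#' Each column has its own scalar mean subtracted and is then scaled to unit
#' Euclidean norm. Columns that are identically zero after mean removal are
#' dropped with a warning.
#'
#' @param X A raw `patch_matrix`.
#' @return A preprocessed `patch_matrix`.
#' @export
preprocess_patches <- function(X) {
  stopifnot(inherits(X, "patch_matrix"))
  if (isTRUE(attr(X, "preprocessed"))) {
    stop_param("patches are already preprocessed")
  }
  ps <- attr(X, "patch_shape"); hop <- attr(X, "hop_ms")
  Xc <- sweep(unclass(X), 2L, colMeans(X), "-")
  norms <- sqrt(colSums(Xc^2))
  keep <- norms > 1e-12
  if (!any(keep)) stop_param("all patches are constant; nothing to preprocess")
  if (!all(keep)) {
    warning(sprintf("dropped %d constant (all-zero after mean removal) patches",
                    sum(!keep)))
    Xc <- Xc[, keep, drop = FALSE]
    norms <- norms[keep]
  }
  Xc <- sweep(Xc, 2L, norms, "/")
  new_patch_matrix(Xc, patch_shape = ps, hop_ms = hop, preprocessed = TRUE)
}

#' Fit a PCA whitening model
#'
#' Eigendecomposes the sample covariance (1/T normalization) of preprocessed
#' patches and retains the smallest number of leading components whose
#' cumulative eigenvalue sum reaches `var_fraction` of the total variance.
#' Near-zero eigenvalues (below `1e-12` of the largest) are discarded.
#'
#' @param X A preprocessed `patch_matrix`.
#' @param var_fraction Fraction of variance to capture (default 0.95).
#' @return A `whitening_model` with fields `eigvecs` (D x M), `eigvals`
#'   (length M, descending), `M`, `D`, and `var_fraction`.
#' @export
fit_whitening <- function(X, var_fraction = 0.95) {
  stopifnot(inherits(X, "patch_matrix"))
  if (!isTRUE(attr(X, "preprocessed"))) {
    stop_param("whitening must be fitted on preprocessed patches")
  }
  check_scalar(var_fraction, "var_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  T_len <- ncol(X)
  C <- tcrossprod(unclass(X)) / T_len
  eig <- eigen(C, symmetric = TRUE)
  pos <- eig$values > 1e-12 * eig$values[1]
  vals <- eig$values[pos]
  vecs <- eig$vectors[, pos, drop = FALSE]
  total <- sum(eig$values[eig$values > 0])
  M <- which(cumsum(vals) >= var_fraction * total)[1]
  if (is.na(M)) M <- length(vals)
  if (T_len <= M) {
    stop_param("need more patches (T = %d) than retained components (M = %d)",
               T_len, M)
  }
  structure(list(eigvecs = vecs[, seq_len(M), drop = FALSE],
                 eigvals = vals[seq_len(M)],
                 M = as.integer(M), D = nrow(X),
                 var_fraction = var_fraction,
                 patch_shape = attr(X, "patch_shape")),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("<whitening_model> D = %d -> M = %d components (%.0f%% variance target)\n",
              x$D, x$M, 100 * x$var_fraction))
  invisible(x)
}

#' Whiten patches with a fitted model
#'
#' Computes `Z = Lambda^(-1/2) E' X`. On the fitting data the sample
#' covariance of `Z` is the identity.
#'
#' @param X A preprocessed `patch_matrix` (fitting or held-out data).
#' @param model A [fit_whitening()] model fitted at the same dimension D.
#' @return An M x T matrix of class `whitened_matrix`.
#' @export
apply_whitening <- function(X, model) {
  stopifnot(inherits(model, "whitening_model"))
  if (inherits(X, "whitened_matrix")) {
    stop_param("input is already whitened; refusing to whiten twice")
  }
  if (inherits(X, "patch_matrix") && !isTRUE(attr(X, "preprocessed"))) {
    stop_param("patches must be preprocessed before whitening")
  }
  check_matrix(X, "X")
  if (nrow(X) != model$D) {
    stop_param("dimension mismatch: patches have D = %d, model expects %d",
               nrow(X), model$D)
  }
  Z <- crossprod(model$eigvecs, unclass(X)) / sqrt(model$eigvals)
  structure(Z, class = c("whitened_matrix", "matrix", "array"),
            patch_shape = attr(X, "patch_shape"))
}

#' Map whitened-space filters back to raw-coordinate STRFs
#'
#' Given a matrix `B` (M x K) with orthonormal columns in whitened
#' coordinates, returns `H = E Lambda^(-1/2) B` so that `H' X = B' Z`.
#' Each column of `H`, reshaped via [unstack_patch()], is an STRF patch, and
#' the ensemble response `H' X` has identity covariance on the fitting data.
#'
#' @param B M x K matrix with orthonormal columns (`B'B = I` within 1e-8).
#' @param model The [fit_whitening()] model used to produce the whitened data.
#' @return A D x K matrix of raw-space filters.
#' @export
unwhiten_filters <- function(B, model) {
  check_matrix(B, "B")
  stopifnot(inherits(model, "whitening_model"))
  if (nrow(B) != model$M) {
    stop_param("B has %d rows; model retains M = %d components",
               nrow(B), model$M)
  }
  resid <- max(abs(crossprod(B) - diag(ncol(B))))
  if (resid > 1e-8) {
    stop_param("B does not have orthonormal columns (residual %.2e > 1e-8)",
               resid)
  }
  model$eigvecs %*% (B / sqrt(model$eigvals))
}
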