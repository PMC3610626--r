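# Grouping canonical STRF classes: cross-correlation similarity, normalized
# spectral clustering, threshold-based merging of noisy/localized clusters,
# and class-distribution entropy.

#' Cross-correlation similarity between two STRF patches
#'
#' Both patches are normalized to unit Frobenius norm, their full 2D
#' cross-correlation over all zero-padded time-frequency shifts is computed,
#' and the similarity is the maximum absolute correlation value, so that
#' excitatory and inhibitory versions of the same pattern are treated as
#' identical. By Cauchy-Schwarz the result lies in `[0, 1]`.
#'
#' @param patch_i,patch_j STRF patch matrices of the same shape.
#' @return Similarity `s` in `[0, 1]`.
#' @export
strf_similarity <- function(patch_i, patch_j) {
  A <- as_strf_patch(patch_i); B <- as_strf_patch(patch_j)
  if (!all(dim(A) == dim(B))) stop_param("patches must have the same shape")
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na < 1e-300 || nb < 1e-300) stop_param("zero patch has undefined similarity")
  max(abs(cross_correlate2d(A / na, B / nb)))
}

# full linear 2D cross-correlation via zero-padded FFTs
cross_correlate2d <- function(A, B) {
  n1 <- nrow(A) + nrow(B) - 1L
  n2 <- ncol(A) + ncol(B) - 1L
  Ap <- matrix(0, n1, n2); Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  Bp <- matrix(0, n1, n2); Bp[seq_len(nrow(B)), seq_len(ncol(B))] <- B
  Re(stats::fft(stats::fft(Ap) * Conj(stats::fft(Bp)), inverse = TRUE)) /
    (n1 * n2)
}

#' Pairwise similarity matrix for a set of STRFs
#'
#' @param patches A list of patch matrices, an `strf_ensemble`, or a filter
#'   matrix (columns unstacked via `patch_shape`).
#' @param patch_shape `c(frames, channels)` for unstacking filter columns.
#' @return A `similarity_matrix`: symmetric n x n matrix with unit diagonal
#'   and entries in `[0, 1]`.
#' @export
similarity_matrix <- function(patches, patch_shape = c(50L, 60L)) {
  patches <- strf_patch_list(patches, patch_shape)
  n <- length(patches)
  if (n < 2L) stop_param("need at least 2 STRFs")
  # precompute padded FFTs once; each pair needs one inverse FFT
  d1 <- nrow(patches[[1]]); d2 <- ncol(patches[[1]])
  n1 <- 2L * d1 - 1L; n2 <- 2L * d2 - 1L
  ffts <- lapply(patches, function(p) {
    if (!all(dim(p) == c(d1, d2))) stop_param("patches must share one shape")
    nrm <- sqrt(sum(p^2))
    if (nrm < 1e-300) stop_param("zero patch has undefined similarity")
    Pp <- matrix(0, n1, n2)
    Pp[seq_len(d1), seq_len(d2)] <- p / nrm
    stats::fft(Pp)
  })
  W <- diag(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cc <- Re(stats::fft(ffts[[i]] * Conj(ffts[[j]]), inverse = TRUE)) /
        (n1 * n2)
      s <- min(max(abs(cc)), 1)
      W[i, j] <- s
      W[j, i] <- s
    }
  }
  structure(W, class = c("similarity_matrix", "matrix", "array"))
}

#' Normalized spectral clustering of a similarity matrix
#'
#' Eigendecomposes the normalized affinity `D^(-1/2) W D^(-1/2)` (`D` the
#' degree matrix), takes the eigenvectors of the `k` largest eigenvalues,
#' normalizes each row to unit Euclidean norm, and clusters the rows with
#' seeded k-means (20 restarts, best within-cluster sum of squares).
#'
#' @param W A `similarity_matrix` (or symmetric non-negative matrix).
#' @param k Number of clusters (default 12), `k < n`.
#' @param seed Integer seed for k-means restarts.
#' @param nstart Number of k-means restarts (default 20).
#' @return Integer vector of cluster labels in `1..k`.
#' @export
spectral_cluster <- function(W, k = 12, seed = 1, nstart = 20) {
  check_matrix(W, "W")
  n <- nrow(W)
  if (k >= n) {
    if (k == n) return(seq_len(n))        # every item its own cluster
    stop_param("need k <= n (k = %d, n = %d)", k, n)
  }
  deg <- rowSums(W)
  if (any(deg <= 1e-12)) {
    stop_param("isolated node(s) with zero degree: %s",
               paste(which(deg <= 1e-12), collapse = ", "))
  }
  dhalf <- 1 / sqrt(deg)
  S <- unclass(W) * tcrossprod(dhalf)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  if (any(rn < 1e-12)) stop_param("degenerate spectral embedding row(s)")
  U <- U / rn
  km <- with_local_seed(seed, stats::kmeans(U, centers = k, nstart = nstart,
                                            iter.max = 100))
  as.integer(km$cluster)
}

#' Merge noisy and localized clusters by mean-metric thresholds
#'
#' Clusters are ranked by mean separability index (SPI) in descending order;
#' the top-ranked clusters whose mean SPI exceeds `spi_threshold` are pooled
#' into one "noisy" class (the pooled group's mean then also exceeds the
#' threshold). Among the remaining clusters the same procedure runs on mean
#' compactness against `q_threshold`, yielding the "localized" class. With
#' 12 initial clusters of which three are noisy and two localized, this
#' produces nine final classes. Labels are relabeled contiguously.
#'
#' @param labels Integer initial cluster labels.
#' @param spi Per-STRF separability indices.
#' @param compactness Per-STRF compactness values (NAs ignored in means).
#' @param spi_threshold Pooled mean SPI threshold (default 0.5).
#' @param q_threshold Pooled mean compactness threshold (default 0.69).
#' @return Integer merged labels with attributes `noisy_class` and
#'   `localized_class` (the merged label ids, or NA when no merge fired).
#' @export
merge_clusters <- function(labels, spi, compactness,
                           spi_threshold = 0.5, q_threshold = 0.69) {
  if (length(labels) != length(spi) || length(labels) != length(compactness)) {
    stop_param("`labels`, `spi` and `compactness` must have equal length")
  }
  labels <- as.integer(labels)
  merge_greedy <- function(labels, metric, threshold) {
    ids <- sort(unique(labels))
    means <- vapply(ids, function(g) mean(metric[labels == g], na.rm = TRUE),
                    numeric(1))
    ord <- order(means, decreasing = TRUE)
    group <- ids[ord][is.finite(means[ord]) & means[ord] > threshold]
    if (length(group) >= 2L) {
      labels[labels %in% group] <- group[1]
      list(labels = labels, merged = group[1])
    } else {
      list(labels = labels, merged = NA_integer_)
    }
  }
  step1 <- merge_greedy(labels, spi, spi_threshold)
  # localized merge runs over the clusters not absorbed into the noisy class
  step2_input <- step1$labels
  if (!is.na(step1$merged)) {
    rest <- step2_input != step1$merged
  } else {
    rest <- rep(TRUE, length(step2_input))
  }
  sub <- merge_greedy(step2_input[rest], compactness[rest], q_threshold)
  step2_input[rest] <- sub$labels
  final <- step2_input
  ids <- sort(unique(final))
  relabel <- match(final, ids)
  structure(as.integer(relabel),
            noisy_class = if (is.na(step1$merged)) NA_integer_ else
              match(step1$merged, ids),
            localized_class = if (is.na(sub$merged)) NA_integer_ else
              match(sub$merged, ids))
}

#' Shannon entropy of a class labeling
#'
#' Entropy (base 2) of the empirical class distribution; `log2(9) ~ 3.17`
#' bits is the maximum for nine equally filled classes.
#'
#' @param labels Vector of class labels.
#' @return Entropy in bits.
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0L) stop_param("need at least one label")
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}
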