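# Shared fixtures and independent oracles used across the test files.

# central finite-difference gradient of a scalar function of a matrix
fd_gradient <- function(f, B, h = 1e-5) {
  G <- B * 0
  for (i in seq_along(B)) {
    Bp <- B; Bm <- B
    Bp[i] <- Bp[i] + h
    Bm[i] <- Bm[i] - h
    G[i] <- (f(Bp) - f(Bm)) / (2 * h)
  }
  G
}

# largest principal angle (degrees) between the column spans of U and V
max_principal_angle <- function(U, V) {
  qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
  max(acos(pmin(svd(crossprod(qu, qv))$d, 1)) * 180 / pi)
}

# greedy one-to-one assignment score: mean |corr| between matched rows
matched_abs_correlation <- function(Y, S) {
  Cm <- abs(stats::cor(t(Y), t(S)))
  used <- integer(0); got <- numeric(0)
  for (i in order(apply(Cm, 1, max), decreasing = TRUE)) {
    j <- order(Cm[i, ], decreasing = TRUE)
    j <- j[!(j %in% used)][1]
    used <- c(used, j)
    got <- c(got, Cm[i, j])
  }
  mean(got)
}

# orthonormally mixed unit-variance Laplacian sources (sparse-coding fixture)
laplacian_mixture <- function(D, T_len, seed) {
  withr::with_seed(seed, {
    S <- matrix(sample(c(-1, 1), D * T_len, TRUE) * stats::rexp(D * T_len),
                D) / sqrt(2)
    S <- S / sqrt(rowMeans(S^2))
    A <- qr.Q(qr(matrix(stats::rnorm(D * D), D)))
    list(S = S, A = A, X = A %*% S)
  })
}

# whiten a plain matrix (1/T covariance convention), for fixtures that are
# not spectrogram patches
whiten_plain <- function(X) {
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > 1e-10 * e$values[1]
  E <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  list(Z = crossprod(E, X) / sqrt(lam), E = E, lam = lam)
}

# drifting-ripple STRF patch cos(2*pi*(rate*t + sgn*scale*f)) on the default
# 5 ms / 10-channel-per-octave grid; direction "down" pairs positive rate
# with positive scale
ripple_patch <- function(rate_hz, scale_cpo, n_t = 50, n_f = 60,
                         direction = c("down", "up"), frame_ms = 5,
                         ch_per_octave = 10) {
  direction <- match.arg(direction)
  sgn <- if (direction == "down") 1 else -1
  tt <- (seq_len(n_t) - 1) * frame_ms / 1000
  ff <- (seq_len(n_f) - 1) / ch_per_octave
  outer(tt, ff, function(t, f) cos(2 * pi * (rate_hz * t + sgn * scale_cpo * f)))
}

# adjusted Rand index between two labelings (closed-form pair-counting oracle)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# signed DFT frequency axis (restated independently of the package internals)
fft_freqs_oracle <- function(n, fs) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k * fs / n
}

# symmetric matrix square root (oracle for A(A'A)^(-1/2))
expm_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
}

# wrap a plain matrix as a (raw or preprocessed) patch_matrix
as_patch_matrix <- function(X, patch_shape = c(nrow(X) %/% 60, 60),
                            preprocessed = FALSE) {
  strfens:::new_patch_matrix(X, patch_shape = patch_shape, hop_ms = 5,
                             preprocessed = preprocessed)
}

# wrap a plain matrix as an auditory spectrogram (frames x channels)
as_spectrogram <- function(values, frame_ms = 5) {
  structure(values, class = c("auditory_spectrogram", "matrix", "array"),
            center_freqs_hz = 62.5 * 2^((0:(ncol(values) - 1)) / 10),
            frame_ms = frame_ms)
}

# mass fraction of an mtf-like object below given |rate| and scale bounds
modulation_mass_below <- function(mtf, rate_max, scale_max, power = 2) {
  E <- mtf$magnitude^power
  sel_r <- abs(mtf$rate_hz) <= rate_max
  sel_s <- mtf$scale_cpo <= scale_max
  sum(E[sel_r, sel_s]) / sum(E)
}
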