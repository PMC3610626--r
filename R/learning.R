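# Objective functions and constrained optimization.
#
# Two population coding objectives are maximized over filter matrices with
# orthonormal columns:
#
#   * sustained:  Psi_s = sum_i sum_{n=1..N} w_n * avg_t [ y_i(t)^2 y_i(t-n)^2 ],
#     the weighted sum of lagged correlations between response energies -- a
#     temporal-slowness (sustained firing) criterion. Weights decay linearly
#     with lag.
#   * sparse:     Psi_k = avg_t [ m4(t) / var(t)^2 ], the raw (non-excess)
#     sample kurtosis of the instantaneous population response, time-averaged.
#
# Optimization is Rosen's gradient projection: a gradient ascent step followed
# by projection onto the set of matrices with orthonormal columns (the
# orthogonal Procrustes solution A (A'A)^(-1/2) = U V'), with step halving
# until the objective is non-decreasing. Under response constraints the data
# are whitened patches and orthonormality of B enforces unit-variance,
# mutually uncorrelated responses; under shape constraints the data are raw
# preprocessed patches and the filters themselves form an orthonormal basis.

#' Configure a learning objective
#'
#' @param kind `"sustained"` or `"sparse"`.
#' @param N_ms Correlation interval in ms for the sustained objective
#'   (typically one of 10, 25, 50, 125, 250, 500, 1000, 2000).
#' @param frame_ms Frame step of the response sampling (default 5 ms).
#' @param weights Optional positive, non-increasing lag weights
#'   `w_1 ... w_{N_lags}`; default linearly decaying
#'   `w_n = (N_lags - n + 1)/N_lags`.
#' @return An `objective_config`.
#' @export
objective_config <- function(kind = c("sustained", "sparse"), N_ms = 125,
                             frame_ms = 5, weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "sustained") {
    check_scalar(N_ms, "N_ms", lower = frame_ms)
    N_lags <- as.integer(round(N_ms / frame_ms))
    if (abs(N_lags - N_ms / frame_ms) > 1e-9) {
      stop_param("`N_ms` must be a multiple of `frame_ms`")
    }
    if (is.null(weights)) {
      weights <- (N_lags - seq_len(N_lags) + 1) / N_lags
    }
    if (length(weights) != N_lags || any(weights <= 0) ||
        any(diff(weights) > 1e-12)) {
      stop_param("`weights` must be %d positive non-increasing values", N_lags)
    }
  } else {
    N_lags <- NA_integer_
    weights <- NULL
  }
  structure(list(kind = kind, N_ms = if (kind == "sustained") N_ms else NA,
                 frame_ms = frame_ms, N_lags = N_lags, weights = weights),
            class = "objective_config")
}

#' Ensemble responses to data
#'
#' `Y = filters' data`: each row is one model neuron's instantaneous
#' firing-rate proxy over time.
#'
#' @param ensemble An `strf_ensemble` (or a plain filter matrix).
#' @param data A matrix in the same coordinate space as the filters
#'   (whitened for response-constrained ensembles, raw patches for
#'   shape-constrained ones).
#' @return A K x T `ResponseMatrix`.
#' @export
compute_responses <- function(ensemble, data) {
  filters <- if (inherits(ensemble, "strf_ensemble")) ensemble$filters else ensemble
  check_matrix(filters, "filters")
  check_matrix(data, "data")
  if (nrow(filters) != nrow(data)) {
    stop_param("coordinate mismatch: filters have %d rows, data has %d",
               nrow(filters), nrow(data))
  }
  crossprod(filters, unclass(data))
}

#' Sustained-firing objective
#'
#' `Psi_s = sum_i sum_n w_n * mean_{t = n+1..T} [ y_i(t)^2 y_i(t-n)^2 ]`.
#'
#' @param Y K x T response matrix.
#' @param config A sustained [objective_config()].
#' @return Scalar objective value.
#' @export
sustained_objective <- function(Y, config) {
  sum(per_filter_scores(Y, config))
}

per_filter_scores <- function(Y, config) {
  stopifnot(inherits(config, "objective_config"), config$kind == "sustained")
  check_matrix(Y, "Y")
  T_len <- ncol(Y)
  if (T_len <= config$N_lags) {
    stop_param("need T > N_lags (T = %d, N_lags = %d)", T_len, config$N_lags)
  }
  Y2 <- Y^2
  scores <- numeric(nrow(Y))
  for (n in seq_len(config$N_lags)) {
    hi <- (n + 1):T_len
    scores <- scores + config$weights[n] *
      rowMeans(Y2[, hi, drop = FALSE] * Y2[, hi - n, drop = FALSE])
  }
  scores
}

#' Gradient of the sustained objective with respect to the filters
#'
#' Analytic gradient of [sustained_objective()] through `Y = B' Z`.
#'
#' @param B m x K filter matrix.
#' @param Z m x T data matrix.
#' @param config A sustained [objective_config()].
#' @return An m x K gradient matrix.
#' @export
sustained_gradient <- function(B, Z, config) {
  stopifnot(inherits(config, "objective_config"), config$kind == "sustained")
  check_matrix(B, "B")
  Z <- unclass(Z)
  Y <- crossprod(B, Z)
  T_len <- ncol(Y)
  if (T_len <= config$N_lags) {
    stop_param("need T > N_lags (T = %d, N_lags = %d)", T_len, config$N_lags)
  }
  Y2 <- Y^2
  Cf <- matrix(0, nrow(Y), T_len)   # per-time gradient coefficients dPsi/dy
  for (n in seq_len(config$N_lags)) {
    hi <- (n + 1):T_len
    lo <- 1:(T_len - n)
    coef <- 2 * config$weights[n] / (T_len - n)
    Cf[, hi] <- Cf[, hi] + coef * Y[, hi, drop = FALSE] * Y2[, lo, drop = FALSE]
    Cf[, lo] <- Cf[, lo] + coef * Y[, lo, drop = FALSE] * Y2[, hi, drop = FALSE]
  }
  Z %*% t(Cf)
}

#' Population-kurtosis (sparsity) objective
#'
#' At each time the raw (non-excess) sample kurtosis of the population
#' response `{y_i(t)}` is computed -- fourth central moment over squared
#' variance -- and averaged over time. Times with population variance below
#' `min_var` are skipped with a warning.
#'
#' @param Y K x T response matrix with K >= 2.
#' @param min_var Degeneracy guard on the population variance.
#' @return Scalar objective value.
#' @export
kurtosis_objective <- function(Y, min_var = 1e-12) {
  km <- kurtosis_moments(Y, min_var)
  mean(km$m4[km$valid] / km$v[km$valid]^2)
}

kurtosis_moments <- function(Y, min_var = 1e-12) {
  check_matrix(Y, "Y")
  if (nrow(Y) < 2L) stop_param("population kurtosis needs K >= 2 neurons")
  m <- colMeans(Y)
  Dm <- sweep(Y, 2L, m, "-")
  v <- colMeans(Dm^2)
  m4 <- colMeans(Dm^4)
  valid <- v >= min_var
  if (!any(valid)) stop_param("population variance is degenerate at every time")
  if (!all(valid)) {
    warning(sprintf("skipped %d time points with degenerate population variance",
                    sum(!valid)))
  }
  list(m = m, D = Dm, v = v, m4 = m4, valid = valid)
}

#' Gradient of the population-kurtosis objective
#'
#' Analytic gradient of [kurtosis_objective()] through `Y = B' Z` (quotient
#' rule over the population moments at each time, averaged over valid times).
#'
#' @param B m x K filter matrix.
#' @param Z m x T data matrix.
#' @param min_var Degeneracy guard on the population variance.
#' @return An m x K gradient matrix.
#' @export
kurtosis_gradient <- function(B, Z, min_var = 1e-12) {
  check_matrix(B, "B")
  Z <- unclass(Z)
  Y <- crossprod(B, Z)
  K <- nrow(Y)
  km <- kurtosis_moments(Y, min_var)
  valid <- km$valid
  n_valid <- sum(valid)
  D3 <- km$D^3
  c3 <- colMeans(D3)
  # d(m4/v^2)/dy_j = (4/K) [ (d_j^3 - mean(d^3))/v^2 - m4 d_j / v^3 ]
  G <- sweep(D3, 2L, c3, "-")
  G <- sweep(G, 2L, km$v^2, "/") -
    sweep(sweep(km$D, 2L, km$m4, "*"), 2L, km$v^3, "/")
  G <- G * (4 / (K * n_valid))
  G[, !valid] <- 0
  Z %*% t(G)
}

#' Project onto the nearest matrix with orthonormal columns
#'
#' The orthogonal Procrustes solution: for full-column-rank `A`,
#' `A (A'A)^(-1/2) = U V'` from the thin SVD `A = U S V'`, which minimizes
#' the Frobenius distance to `A` over all matrices with orthonormal columns.
#'
#' @param A An m x k matrix, `m >= k`, full column rank.
#' @return The m x k projection with orthonormal columns.
#' @export
procrustes_project <- function(A) {
  check_matrix(A, "A")
  if (nrow(A) < ncol(A)) stop_param("need m >= k for orthonormal columns")
  s <- svd(A)
  rank <- sum(s$d > max(s$d[1], 1e-300) * 1e-12)
  if (rank < ncol(A)) {
    stop_param("A is rank deficient (rank %d < %d columns)", rank, ncol(A))
  }
  s$u %*% t(s$v)
}

#' Fit an STRF ensemble by projected gradient ascent
#'
#' Rosen's gradient projection method: starting from a seeded Gaussian random
#' matrix projected to orthonormal columns, iterate
#' `B <- procrustes_project(B + mu * 2^(-k) * grad Psi(B))`, where the
#' halving exponent `k` starts at 0 each outer iteration and is incremented
#' while the candidate would decrease the objective. Learning stops when the
#' relative objective change falls below `tol`, after `max_iter` iterations,
#' or when step halving is exhausted.
#'
#' @param data For `mode = "response"`, a `whitened_matrix` (see
#'   [apply_whitening()]); for `mode = "shape"`, a preprocessed
#'   `patch_matrix`. A plain matrix is accepted for synthetic fixtures.
#' @param K Ensemble size (number of filters; default 400).
#' @param objective An [objective_config()].
#' @param mode `"response"` (orthonormal filters in whitened space, giving
#'   unit-variance uncorrelated responses) or `"shape"` (orthonormal filters
#'   in raw patch space).
#' @param mu Base learning rate. The default (`NULL`) auto-scales it so the
#'   first gradient step has Frobenius norm `sqrt(K)` (comparable to the
#'   filter matrix itself); step halving then shrinks overshooting steps.
#'   Auto-scaling matters because gradient magnitudes differ by orders of
#'   magnitude between whitened and raw coordinates.
#' @param max_iter Maximum outer iterations (default 30).
#' @param tol Relative objective-change stopping tolerance (default 1e-4).
#' @param seed Integer seed for the random initialization.
#' @param max_halvings Step-halving budget per iteration (default 50).
#' @param whitening Optional [fit_whitening()] model; when supplied with
#'   `mode = "response"`, raw-space STRFs are attached as `$strfs`.
#' @return An `strf_ensemble` with fields `filters` (orthonormal columns),
#'   `coordinate_space`, `constraint_mode`, `objective`, `seed`, `trace`
#'   (a `trace_record` data.frame), and optionally `strfs`.
#' @export
fit_ensemble <- function(data, K = 400, objective = objective_config(),
                         mode = c("response", "shape"), mu = NULL,
                         max_iter = 30, tol = 1e-4, seed = 1,
                         max_halvings = 50, whitening = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(objective, "objective_config"))
  if (mode == "response" && inherits(data, "patch_matrix")) {
    stop_param("response constraints require whitened data; see apply_whitening()")
  }
  if (mode == "shape" && inherits(data, "patch_matrix") &&
      !isTRUE(attr(data, "preprocessed"))) {
    stop_param("shape constraints require preprocessed patches")
  }
  check_matrix(data, "data")
  m <- nrow(data)
  if (K > m) stop_param("K = %d filters cannot be orthonormal in dimension %d",
                        K, m)
  Zd <- unclass(data)
  obj_fun <- function(B) {
    Y <- crossprod(B, Zd)
    if (objective$kind == "sustained") {
      sustained_objective(Y, objective)
    } else {
      suppressWarnings(kurtosis_objective(Y))
    }
  }
  grad_fun <- function(B) {
    if (objective$kind == "sustained") {
      sustained_gradient(B, Zd, objective)
    } else {
      suppressWarnings(kurtosis_gradient(B, Zd))
    }
  }
  B <- with_local_seed(seed, matrix(stats::rnorm(m * K), m, K))
  B <- procrustes_project(B)
  psi <- obj_fun(B)
  if (is.null(mu)) {
    g0 <- sqrt(sum(grad_fun(B)^2))
    mu <- if (g0 > 0) sqrt(K) / g0 else 1
  }
  trace_val <- psi
  trace_resid <- max(abs(crossprod(B) - diag(K)))
  trace_halv <- 0L
  stop_reason <- "max_iter"
  for (iter in seq_len(max_iter)) {
    g <- grad_fun(B)
    k <- 0L
    repeat {
      cand <- procrustes_project(B + mu * 2^(-k) * g)
      psi_cand <- obj_fun(cand)
      if (psi_cand >= psi || k >= max_halvings) break
      k <- k + 1L
    }
    if (psi_cand < psi) {
      # halving exhausted without a non-decreasing step: stay at B
      stop_reason <- "step_halving_exhausted"
      break
    }
    rel_change <- (psi_cand - psi) / max(abs(psi), .Machine$double.eps)
    B <- cand
    psi <- psi_cand
    trace_val <- c(trace_val, psi)
    trace_resid <- c(trace_resid, max(abs(crossprod(B) - diag(K))))
    trace_halv <- c(trace_halv, k)
    if (rel_change < tol) {
      stop_reason <- "tol"
      break
    }
  }
  trace <- structure(data.frame(iteration = seq_along(trace_val) - 1L,
                                objective = trace_val,
                                constraint_residual = trace_resid,
                                halvings = trace_halv),
                     class = c("trace_record", "data.frame"),
                     stop_reason = stop_reason)
  ens <- structure(list(filters = B, K = as.integer(K),
                        coordinate_space = if (mode == "response") "whitened" else "raw",
                        constraint_mode = mode, objective = objective,
                        mu = mu, tol = tol, seed = as.integer(seed),
                        trace = trace,
                        patch_shape = attr(data, "patch_shape")),
                   class = "strf_ensemble")
  if (mode == "response" && !is.null(whitening)) {
    ens$strfs <- unwhiten_filters(B, whitening)
    ens$patch_shape <- whitening$patch_shape
  } else if (mode == "shape") {
    ens$strfs <- B
  }
  ens
}

#' @export
print.strf_ensemble <- function(x, ...) {
  cat(sprintf("<strf_ensemble> K = %d %s-constrained filters (%s objective%s)\n",
              x$K, x$constraint_mode, x$objective$kind,
              if (x$objective$kind == "sustained")
                sprintf(", N = %g ms", x$objective$N_ms) else ""))
  cat(sprintf("  %d accepted iterations, stop: %s, final objective %.6g\n",
              nrow(x$trace) - 1L, attr(x$trace, "stop_reason"),
              x$trace$objective[nrow(x$trace)]))
  invisible(x)
}

#' Per-filter contributions to the sustained objective
#'
#' The sustained objective is a sum of independent per-filter terms, so the
#' emergent STRFs can be sorted by their contribution. (The population
#' kurtosis objective does not decompose this way, and is rejected.)
#'
#' @param ensemble An `strf_ensemble` trained with the sustained objective.
#' @param Y K x T response matrix of that ensemble.
#' @param config The sustained [objective_config()] used in training.
#' @return A data.frame with columns `filter` (original index) and `score`,
#'   sorted by descending score; scores sum to the objective value.
#' @export
per_filter_contribution <- function(ensemble, Y, config) {
  if (inherits(ensemble, "strf_ensemble") &&
      ensemble$objective$kind != "sustained") {
    stop_param("per-filter contributions are only defined for the sustained objective")
  }
  if (config$kind != "sustained") {
    stop_param("per-filter contributions are only defined for the sustained objective")
  }
  scores <- per_filter_scores(Y, config)
  ord <- order(scores, decreasing = TRUE)
  data.frame(filter = ord, score = scores[ord])
}
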