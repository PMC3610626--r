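test_that("responses are inner products and agree with an explicit loop", {
  withr::with_seed(1, {
    Z <- matrix(rnorm(5 * 12), 5)
    B <- matrix(rnorm(5 * 3), 5)
  })
  Y <- compute_responses(B, Z)
  # brute-force per-patch dot products
  Y_loop <- matrix(0, 3, 12)
  for (i in 1:3) for (t in 1:12) Y_loop[i, t] <- sum(B[, i] * Z[, t])
  expect_equal(Y, Y_loop, tolerance = 1e-12)
  expect_equal(compute_responses(diag(5), Z), Z, ignore_attr = TRUE)
  # a filter equal to a unit-norm data column responds with exactly 1 there
  Zu <- sweep(Z, 2L, sqrt(colSums(Z^2)), "/")
  expect_equal(drop(compute_responses(matrix(Zu[, 4]), Zu))[4], 1,
               tolerance = 1e-12)
  expect_error(compute_responses(B, matrix(0, 4, 2)), "mismatch")
})

test_that("sustained objective matches hand values and a triple-loop oracle", {
  cfg1 <- objective_config("sustained", N_ms = 5, frame_ms = 5,
                           weights = 1)                       # single lag, w=1
  expect_equal(sustained_objective(matrix(c(1, -1, 1, -1), 1), cfg1), 1)
  expect_equal(sustained_objective(matrix(c(sqrt(2), 0, sqrt(2), 0), 1), cfg1), 0)
  expect_error(sustained_objective(matrix(1, 1, 1), cfg1), "N_lags")

  cfg3 <- objective_config("sustained", N_ms = 15, frame_ms = 5)
  withr::with_seed(2, Y <- matrix(rnorm(4 * 30), 4))
  naive <- 0
  for (i in 1:4) for (n in 1:3) {
    acc <- 0
    for (t in (n + 1):30) acc <- acc + Y[i, t]^2 * Y[i, t - n]^2
    naive <- naive + cfg3$weights[n] * acc / (30 - n)
  }
  expect_equal(sustained_objective(Y, cfg3), naive, tolerance = 1e-12)
})

test_that("objective_config validates the lag grid and weights", {
  cfg <- objective_config("sustained", N_ms = 125)
  expect_equal(cfg$N_lags, 25L)
  expect_equal(cfg$weights, (25:1) / 25)
  expect_error(objective_config("sustained", N_ms = 12), "multiple")
  expect_error(objective_config("sustained", N_ms = 10, weights = c(1, 2)),
               "non-increasing")
  expect_true(is.na(objective_config("sparse")$N_lags))
})

test_that("analytic gradients match central finite differences", {
  cfg <- objective_config("sustained", N_ms = 15, frame_ms = 5)
  for (rep in 1:5) {
    withr::with_seed(rep, {
      Z <- matrix(rnorm(6 * 40), 6)
      B <- matrix(rnorm(6 * 3), 6)
    })
    g <- sustained_gradient(B, Z, cfg)
    g_fd <- fd_gradient(function(B) sustained_objective(crossprod(B, Z), cfg), B)
    expect_lt(max(abs(g - g_fd)) / max(abs(g_fd)), 1e-5)
  }
  for (rep in 1:5) {
    withr::with_seed(rep + 50, {
      Z <- matrix(rnorm(6 * 40), 6)
      B <- matrix(rnorm(6 * 5), 6)        # K = 5: non-degenerate kurtosis
    })
    g <- kurtosis_gradient(B, Z)
    g_fd <- fd_gradient(function(B) kurtosis_objective(crossprod(B, Z)), B)
    expect_lt(max(abs(g - g_fd)) / max(abs(g_fd)), 1e-5)
  }
})

test_that("gradient structure: zeros, permutation equivariance, duplication", {
  cfg <- objective_config("sustained", N_ms = 10, frame_ms = 5)
  withr::with_seed(3, Z <- matrix(rnorm(5 * 30), 5))
  B0 <- matrix(0, 5, 2)
  expect_equal(sustained_gradient(B0, Z, cfg), B0)

  withr::with_seed(4, B <- matrix(rnorm(5 * 4), 5))
  perm <- c(3, 1, 4, 2)
  g <- sustained_gradient(B, Z, cfg)
  expect_equal(sustained_gradient(B[, perm], Z, cfg), g[, perm],
               tolerance = 1e-12)
  gk <- kurtosis_gradient(B, Z)
  expect_equal(kurtosis_gradient(B[, perm], Z), gk[, perm], tolerance = 1e-12)
  # duplicating the data duplicates the per-time contributions; under the
  # time average the gradient is unchanged
  expect_equal(kurtosis_gradient(B, cbind(Z, Z)), gk, tolerance = 1e-12)
})

test_that("population kurtosis matches hand values and the Gaussian limit", {
  expect_equal(kurtosis_objective(matrix(c(1, 1, -1, -1))), 1)
  expect_equal(kurtosis_objective(matrix(c(3, -1, -1, -1))), 21 / 9)
  withr::with_seed(5, Yg <- matrix(rnorm(1e4 * 3), 1e4, 3))
  expect_equal(kurtosis_objective(Yg), 3, tolerance = 0.1)
  # a constant population instant is skipped with a warning
  Y <- cbind(c(1, 1, 1), c(3, -1, -2))
  expect_warning(v <- kurtosis_objective(Y), "skipped 1")
  expect_equal(v, kurtosis_objective(cbind(c(3, -1, -2))))
  expect_error(kurtosis_objective(matrix(1, 1, 4)), "K >= 2")
})

test_that("Procrustes projection is the closest orthonormal-column matrix", {
  withr::with_seed(6, Q <- qr.Q(qr(matrix(rnorm(30), 6, 5))))
  expect_equal(procrustes_project(Q), Q, tolerance = 1e-12)
  expect_equal(procrustes_project(diag(c(2, 5))), diag(2), tolerance = 1e-12)
  expect_error(procrustes_project(cbind(1:4, 2 * (1:4))), "rank deficient")

  withr::with_seed(7, A <- matrix(rnorm(18), 6, 3))
  P <- procrustes_project(A)
  expect_lt(max(abs(crossprod(P) - diag(3))), 1e-12)
  expect_equal(P, A %*% solve(expm_sqrt(crossprod(A))), tolerance = 1e-10)
  d_best <- sqrt(sum((A - P)^2))
  d_random <- withr::with_seed(8, replicate(1000, {
    R <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
    sqrt(sum((A - R)^2))
  }))
  expect_true(all(d_best <= d_random + 1e-12))
})

test_that("projected gradient ascent is monotone and feasible in all modes", {
  withr::with_seed(10, Zbase <- matrix(rnorm(10 * 300), 10))
  for (kind in c("sustained", "sparse")) {
    for (mode in c("response", "shape")) {
      obj <- if (kind == "sustained") {
        objective_config("sustained", N_ms = 25)
      } else objective_config("sparse")
      data <- if (mode == "response") whiten_plain(Zbase)$Z else {
        as_patch_matrix(Zbase, patch_shape = c(2, 5), preprocessed = TRUE)
      }
      for (seed in 1:3) {
        ens <- fit_ensemble(data, K = 4, objective = obj, mode = mode,
                            seed = seed, max_iter = 10)
        expect_true(all(diff(ens$trace$objective) >= 0))
        expect_true(all(ens$trace$constraint_residual < 1e-8))
      }
    }
  }
})

test_that("response-mode training yields unit-variance responses and raw STRFs", {
  withr::with_seed(11, X <- matrix(rnorm(12 * 2000), 12))
  Xp <- as_patch_matrix(X, patch_shape = c(3, 4), preprocessed = TRUE)
  wm <- fit_whitening(Xp, var_fraction = 1.0)
  Z <- apply_whitening(Xp, wm)
  ens <- fit_ensemble(Z, K = 3, objective = objective_config("sustained", N_ms = 10),
                      mode = "response", seed = 2, max_iter = 5, whitening = wm)
  Y_raw <- crossprod(ens$strfs, unclass(Xp))
  # decorrelated unit-variance responses in raw coordinates (1/T convention)
  expect_lt(max(abs(tcrossprod(Y_raw) / ncol(Y_raw) - diag(3))), 1e-3)
  expect_error(fit_ensemble(Xp, K = 3, mode = "response"), "whitened")
  expect_error(fit_ensemble(Z, K = 50, mode = "response"),
               "cannot be orthonormal")
})

test_that("the sustained objective recovers a planted slow subspace", {
  hits <- 0
  for (seed in 1:3) {
    fix <- gen_slow_latent_patches(20, 4000, n_slow = 4, n_fast = 16,
                                   mixing_seed = seed)
    wp <- whiten_plain(fix$X)
    ens <- fit_ensemble(wp$Z, K = 4,
                        objective = objective_config("sustained", N_ms = 25),
                        mode = "response", seed = seed, max_iter = 500,
                        tol = 1e-10, mu = 10)
    H <- wp$E %*% (ens$filters / sqrt(wp$lam))
    if (max_principal_angle(H, fix$slow_basis) < 10) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("per-filter contributions decompose the sustained objective", {
  cfg <- objective_config("sustained", N_ms = 15, frame_ms = 5)
  withr::with_seed(12, {
    Z <- matrix(rnorm(8 * 200), 8)
    B <- qr.Q(qr(matrix(rnorm(8 * 3), 8)))
  })
  Y <- crossprod(B, Z)
  ens <- list(objective = cfg)
  class(ens) <- "strf_ensemble"
  contrib <- per_filter_contribution(ens, Y, cfg)
  expect_true(all(diff(contrib$score) <= 0))
  expect_true(all(contrib$score >= 0))
  expect_equal(sum(contrib$score), sustained_objective(Y, cfg),
               tolerance = 1e-10)
  # single filter: the score is the whole objective
  c1 <- per_filter_contribution(ens, Y[1, , drop = FALSE], cfg)
  expect_equal(c1$score, sustained_objective(Y[1, , drop = FALSE], cfg))
  # sign flip of a filter leaves energy-based scores unchanged
  Yf <- Y; Yf[2, ] <- -Yf[2, ]
  cf <- per_filter_contribution(ens, Yf, cfg)
  expect_equal(cf$score, contrib$score, tolerance = 1e-12)
  ens_sparse <- structure(list(objective = objective_config("sparse")),
                          class = "strf_ensemble")
  expect_error(per_filter_contribution(ens_sparse, Y, cfg), "sustained")
})
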