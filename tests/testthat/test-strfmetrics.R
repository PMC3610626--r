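test_that("separability index matches its singular-value definition", {
  u <- sin(seq_len(50)); v <- cos(seq_len(60))
  expect_equal(separability_index(outer(u, v)), 0, tolerance = 1e-10)
  # two equal singular values -> 0.5; sigma^2 = {4, 1} -> 0.2
  P2 <- diag(c(1, 1)); P2 <- rbind(cbind(P2, matrix(0, 2, 4)), matrix(0, 3, 6))
  expect_equal(separability_index(P2), 0.5)
  P3 <- matrix(0, 5, 6); P3[1, 1] <- 2; P3[2, 2] <- 1
  expect_equal(separability_index(P3), 0.2)
  # invariances: transposition and scalar scaling
  withr::with_seed(1, P <- matrix(rnorm(50 * 60), 50))
  expect_equal(separability_index(P), separability_index(t(P)))
  expect_equal(separability_index(P), separability_index(-3.7 * P))
  expect_error(separability_index(matrix(0, 5, 5)), "all-zero")
})

test_that("the MTF has the stated axes, handles degenerate patches, and conserves energy", {
  expect_warning(m0 <- compute_mtf(matrix(1, 50, 60)), "zero variance")
  expect_true(all(m0$magnitude == 0))

  m <- suppressWarnings(compute_mtf(ripple_patch(12, 0.5), threshold_sd = 1))
  expect_equal(sort(unique(diff(m$rate_hz))), 4)          # 1/(0.25 s) grid
  expect_equal(max(abs(m$rate_hz)), 100)
  expect_equal(diff(m$scale_cpo)[1], 1 / 6, tolerance = 1e-12)
  expect_equal(max(m$scale_cpo), 5)
  expect_true(all(m$magnitude >= 0))

  # Parseval: spectrum energy (half-plane doubled, unpaired columns single)
  # equals n_cells times the thresholded-patch energy
  w <- rep(2, ncol(m$magnitude)); w[1] <- 1; w[length(w)] <- 1
  expect_equal(sum(m$magnitude^2 %*% w), m$n_cells * m$thresholded_energy,
               tolerance = 1e-8)

  # MTF is invariant to patch sign flip
  p <- ripple_patch(8, 1)
  expect_equal(compute_mtf(p)$magnitude, compute_mtf(-p)$magnitude,
               tolerance = 1e-10)
})

test_that("best rate/scale recover planted ripple parameters within one bin", {
  for (rate in c(8, 24, 40)) {
    for (scale in c(0.5, 1.5, 2.5)) {
      brbs <- best_rate_scale(compute_mtf(ripple_patch(rate, scale)))
      expect_lte(abs(brbs[["br_hz"]] - rate), 4)
      expect_lte(abs(brbs[["bs_cpo"]] - scale), 1 / 6)
    }
  }
  # purely temporal pattern: best scale in the lowest scale bin
  p_t <- matrix(rep(cos(2 * pi * 12 * (0:49) * 0.005), 60), 50)
  brbs <- best_rate_scale(compute_mtf(p_t, threshold_sd = 0))
  expect_equal(brbs[["bs_cpo"]], 0)
  expect_equal(brbs[["br_hz"]], 12)
  # symmetric double peak at +/- rate reports the magnitude
  p_sep <- outer(cos(2 * pi * 12 * (0:49) * 0.005), cos(2 * pi * 1 * (0:59) / 10))
  expect_equal(best_rate_scale(compute_mtf(p_sep, threshold_sd = 0))[["br_hz"]], 12)
})

test_that("modulation profiles peak at the ripple rate and interpolate 6-dB cutoffs", {
  prof <- modulation_profiles(compute_mtf(ripple_patch(10, 0.5)))
  peak_rate <- prof$rate$axis[which.max(prof$rate$profile)]
  expect_true(peak_rate >= 8 && peak_rate <= 12)
  expect_lte(prof$rate_cutoff6dB_hz, 100)
  expect_gte(prof$rate_cutoff6dB_hz, peak_rate)

  # hand-interpolated cutoff for a single-bin profile: crossing between the
  # peak bin and the next, at amplitude 10^(-6/20)
  axis <- c(0, 4, 8, 12)
  profile <- c(0, 1, 0, 0)
  cut <- strfens:::profile_cutoff(axis, profile)
  expect_equal(cut, 4 + (1 - 10^(-6 / 20)) * 4, tolerance = 1e-12)

  # flat profile: cutoff at axis maximum with a warning
  expect_warning(cut_flat <- strfens:::profile_cutoff(axis, rep(1, 4)),
                 "never falls")
  expect_equal(cut_flat, 12)
  # all-ones MTF: the scale profile is exactly flat (cutoff at the axis max,
  # with a warning); the folded rate profile dips only at the unpaired
  # Nyquist row, so its cutoff sits in the last bin
  flat <- structure(list(magnitude = matrix(1, 50, 31),
                         rate_hz = sort(fft_freqs_oracle(50, 200)),
                         scale_cpo = (0:30) / 6), class = "mtf")
  expect_warning(pf <- modulation_profiles(flat), "never falls")
  expect_equal(pf$scale_cutoff6dB_cpo, 5)
  expect_gte(pf$rate_cutoff6dB_hz, 96)
})

test_that("directionality separates drift directions and vanishes for separable patches", {
  # separable patch: quadrant symmetry gives exactly zero
  p_sep <- outer(sin(2 * pi * 8 * (0:49) * 0.005) + 0.3,
                 cos(2 * pi * 0.8 * (0:59) / 10))
  expect_equal(directionality_index(compute_mtf(p_sep, threshold_sd = 0)), 0,
               tolerance = 1e-10)
  # single-direction ripples (on the Fourier grid so spectral leakage does
  # not bleed across quadrants): downward -> positive, upward -> negative
  dsi_down <- directionality_index(compute_mtf(ripple_patch(8, 0.5, direction = "down")))
  dsi_up <- directionality_index(compute_mtf(ripple_patch(8, 0.5, direction = "up")))
  expect_gt(dsi_down, 0.95)
  expect_lt(dsi_up, -0.95)
  expect_lte(abs(dsi_down), 1)
  expect_warning(expect_true(is.na(
    directionality_index(suppressWarnings(compute_mtf(matrix(1, 50, 60)))))),
    "undefined")
})

test_that("compactness is 1 for isotropic blobs and follows the ellipse oracle", {
  gauss_blob <- function(st, sf, n_t = 50, n_f = 60) {
    outer(seq_len(n_t), seq_len(n_f), function(t, f) {
      exp(-((t - 25)^2 / (2 * st^2) + (f - 30)^2 / (2 * sf^2)))
    })
  }
  expect_equal(compactness(gauss_blob(5, 5)), 1, tolerance = 0.02)

  # 5:1 elongated blob: closed-form ellipse area/perimeter oracle
  q0 <- log(10^(10 / 20))
  a <- sqrt(2 * q0) * 3; b <- sqrt(2 * q0) * 15
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  q_oracle <- 4 * pi * (pi * a * b) / per^2
  expect_equal(compactness(gauss_blob(3, 15)), q_oracle, tolerance = 0.05)
  expect_true(q_oracle > 0 && q_oracle < 0.5)

  # bounds on valid fits
  withr::with_seed(3, {
    for (i in 1:3) {
      q <- compactness(gauss_blob(runif(1, 2, 8), runif(1, 2, 12)))
      expect_true(q > 0 && q <= 1 + 1e-6)
    }
  })
  expect_warning(expect_true(is.na(compactness(matrix(0, 50, 60)))),
                 "undefined")
})

test_that("strf_metrics returns one labeled row per STRF", {
  patches <- list(ripple_patch(8, 0.5), ripple_patch(24, 1.5, direction = "up"))
  tab <- strf_metrics(patches)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("id", "spi", "br_hz", "bs_cpo", "dsi", "compactness",
                      "rate_cutoff6dB_hz", "scale_cutoff6dB_cpo"))
  expect_lte(abs(tab$br_hz[1] - 8), 4)
  expect_lte(abs(tab$bs_cpo[2] - 1.5), 1 / 6)
  expect_gt(tab$dsi[1], 0.9)
  expect_lt(tab$dsi[2], -0.9)
})
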