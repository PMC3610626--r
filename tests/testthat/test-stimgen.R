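test_that("moving ripples are deterministic, validated, and carry the planted modulation", {
  w1 <- gen_moving_ripple(10, 0.5, 1, "down", seed = 7)
  w2 <- gen_moving_ripple(10, 0.5, 1, "down", seed = 7)
  expect_identical(w1$samples, w2$samples)
  expect_equal(sqrt(mean(w1$samples^2)), 1, tolerance = 1e-10)
  expect_error(gen_moving_ripple(150, 0.5, 1), "outside the allowed range")
  expect_error(gen_moving_ripple(10, 8, 1), "outside the allowed range")

  # planted (rate, scale) recovered within one modulation bin by the 2D FFT
  # of the front-end spectrogram (independent analysis path)
  spec <- compute_spectrogram(gen_moving_ripple(10, 0.5, 3, "down", seed = 2))
  prof <- stimulus_modulation_profile(spec)
  mag <- prof$magnitude
  mag[prof$rate_hz == 0, 1] <- 0                       # drop DC
  idx <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  expect_lte(abs(abs(prof$rate_hz[idx[1]]) - 10), 4)
  expect_lte(abs(prof$scale_cpo[idx[2]] - 0.5), 1 / 6)

  # static ripple: temporal modulation energy concentrated at 0 Hz
  spec0 <- compute_spectrogram(gen_moving_ripple(0, 0.5, 3, seed = 3))
  prof0 <- stimulus_modulation_profile(spec0)
  E <- prof0$magnitude^2
  expect_gt(sum(E[prof0$rate_hz == 0, ]) / sum(E), 0.5)
})

test_that("harmonic calls place stationary ridges at harmonics and AM at the stated rate", {
  expect_error(gen_harmonic_call(numeric(0), 500, 0, 1), "non-empty")
  expect_error(gen_harmonic_call(200, 500, 0, 0), "outside the allowed range")

  w <- gen_harmonic_call(200, formant_centers = c(400, 1600), am_rate_hz = 0,
                         duration_s = 2, seed = 5)
  spec <- compute_spectrogram(w)
  am <- apply(unclass(spec), 1, which.max)
  # stationary: dominant channel constant across frames
  expect_gte(mean(am == stats::median(am)), 0.95)
  # the dominant channel sits on a harmonic of 200 Hz
  fc <- attr(spec, "center_freqs_hz")
  harmonic_freqs <- 200 * (1:19)
  expect_lte(min(abs(log2(fc[stats::median(am)] / harmonic_freqs))), 0.08)

  # amplitude modulation at 4 Hz appears in the spectrogram rate profile
  w4 <- gen_harmonic_call(200, 800, am_rate_hz = 4, duration_s = 3, seed = 5)
  prof <- stimulus_modulation_profile(compute_spectrogram(w4))
  rate_energy <- rowSums(prof$magnitude^2)
  rate_energy[prof$rate_hz == 0] <- 0
  peak_rate <- abs(prof$rate_hz[which.max(rate_energy)])
  expect_lte(abs(peak_rate - 4), 4)
})

test_that("modulated noise is reproducible and low-pass below its cutoffs", {
  expect_error(gen_modulated_noise(0, 0.5, 1), "outside the allowed range")
  w1 <- gen_modulated_noise(4, 0.5, 2, seed = 11)
  w2 <- gen_modulated_noise(4, 0.5, 2, seed = 11)
  expect_identical(w1$samples, w2$samples)

  spec <- compute_spectrogram(gen_modulated_noise(4, 0.5, 5, seed = 11))
  prof <- stimulus_modulation_profile(spec)
  expect_gte(modulation_mass_below(prof, rate_max = 4, scale_max = 0.5), 0.8)
})

test_that("stimulus ensembles honor fractions, standardization, and seeded order", {
  rec <- stimulus_recipe(total_duration_s = 24, seed = 4)
  wav <- gen_stimulus_ensemble(rec)
  seg <- attr(wav, "segments")
  expect_equal(nrow(seg), 8)
  expect_equal(unname(table(seg$class)[c("speech", "vocalization", "ambient")]),
               c(4L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(length(wav$samples), 24 * 8000)

  # segments are standardized before tapering
  raw_seg <- strfens:::gen_segment("speech", 3, seed = 123)
  std <- strfens:::standardize_segment(raw_seg)
  expect_lt(abs(mean(std)), 1e-6)
  expect_equal(stats::sd(std), 1, tolerance = 1e-6)

  # determinism and seed sensitivity of the segment order
  wav_same <- gen_stimulus_ensemble(stimulus_recipe(total_duration_s = 24, seed = 4))
  expect_identical(wav$samples, wav_same$samples)
  seg_other <- attr(gen_stimulus_ensemble(
    stimulus_recipe(total_duration_s = 24, seed = 5)), "segments")
  expect_false(identical(seg$class, seg_other$class))

  expect_error(gen_stimulus_ensemble(
    stimulus_recipe(total_duration_s = 24, class_fractions = c(0.5, 0.3, 0.3))),
    "summing to 1")
  expect_error(stimulus_recipe(total_duration_s = 1), "at least one segment")
})

test_that("ensemble stimuli concentrate modulation energy at low rates and scales", {
  wav <- gen_stimulus_ensemble(stimulus_recipe(total_duration_s = 30, seed = 1))
  prof <- stimulus_modulation_profile(compute_spectrogram(wav))
  expect_gte(modulation_mass_below(prof, rate_max = 20, scale_max = 1), 0.6)
})

test_that("slow-latent patch fixtures plant a recoverable slow subspace", {
  fix <- gen_slow_latent_patches(12, 3000, n_slow = 3, n_fast = 6,
                                 mixing_seed = 9)
  expect_equal(crossprod(fix$mixing), diag(9), tolerance = 1e-10)
  expect_equal(dim(fix$X), c(12, 3000))

  # lag-1 energy autocorrelation: slow sources near the 0.95 target, fast ~ 0
  e_ac <- apply(fix$sources, 1, function(s) {
    e <- s^2
    stats::cor(e[-1], e[-length(e)])
  })
  expect_true(all(e_ac[1:3] > 0.9))
  expect_true(all(abs(e_ac[4:9]) < 0.15))
  expect_true(all(e_ac[1:3] > max(e_ac[4:9])))

  # all-slow case: any unit-norm filter output has high energy autocorrelation
  all_slow <- gen_slow_latent_patches(6, 3000, n_slow = 6, n_fast = 0,
                                      mixing_seed = 2)
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  y <- drop(crossprod(v, all_slow$X))
  e <- y^2
  expect_gt(stats::cor(e[-1], e[-length(e)]), 0.7)

  expect_error(gen_slow_latent_patches(0, 100, 1, 0), "positive integer")
  expect_error(gen_slow_latent_patches(4, 100, 3, 3), "must not exceed D")
})
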