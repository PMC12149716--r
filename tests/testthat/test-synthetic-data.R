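test_that("profile generator is normalized, symmetric and deterministic", {
  sp <- field_spec(10)
  pr <- make_profile(sp, "crossline", n_points = 81)
  expect_equal(max(pr$value), 1)
  expect_equal(pr$value[pr$position_mm == 0], 1)
  expect_equal(pr$value, rev(pr$value))                 # symmetric, no offset
  # zero noise: seeds irrelevant
  p1 <- make_profile(sp, "inline", rng_seed = 1)
  p2 <- make_profile(sp, "inline", rng_seed = 99)
  expect_identical(p1, p2)
  expect_error(field_spec(0), "positive")
  expect_error(field_spec(1, penumbra_sigma = -1), "positive")
  expect_error(make_profile(sp, n_points = 9), ">= 11")
})

test_that("profile FWHM matches dense root finding on the generator", {
  sp <- field_spec(0.6, penumbra_sigma = 2)
  pr <- make_profile(sp, "crossline", n_points = 2001, half_range = 10)
  meas <- smallfieldOF:::.profile_fwhm(pr$position_mm, pr$value)[["fwhm"]]
  expect_lt(abs(meas - analytic_fwhm(sp, "x")[["fwhm"]]), 0.05)
})

test_that("noiseless unit-nuisance sessions reproduce the generating OF", {
  sides <- c(0.6, 1, 2, 10)
  specs <- lapply(sides, field_spec)
  ses <- make_session(specs, session_spec("det", "PSD",
                                          reading_noise_rel = 0,
                                          n_repeats = 1))
  tr <- attr(ses, "truth")
  ratios <- ses$reading / ses$reading[ses$field_side_cm == 10]
  expect_equal(ratios, tr$of, tolerance = 1e-12)
})

test_that("session recombination injection follows the linearized model", {
  sides <- c(0.6, 1, 2, 10)
  specs <- lapply(sides, field_spec)
  B <- 0.0035
  ses <- make_session(specs, session_spec("razor-like", "IC", true_B = B,
                                          reading_noise_rel = 0,
                                          n_repeats = 1))
  tr <- attr(ses, "truth")
  plus <- ses$reading[ses$polarity == "+"]
  r_raw <- plus / plus[sides == 10]
  # applying the model correction recovers the response ratio exactly
  expect_equal(r_raw * kion_ratio(B, r_raw), tr$rho, tolerance = 1e-12)
  # a reading-ratio drop to 0.5 implies the printed injected factor
  expect_equal(kion_ratio(B, 0.5), 1 / (1 + B * (1 - 0.5)))
})

test_that("mean-ratio standard error scales as sigma over sqrt(n)", {
  sides <- c(5, 10)
  specs <- lapply(sides, field_spec)
  set.seed(42)
  ratios <- replicate(150, {
    ses <- make_session(specs, session_spec(
      "psd", "PSD", reading_noise_rel = 0.001, n_repeats = 14,
      rng_seed = sample.int(2^30, 1)))
    m5 <- mean(ses$reading[ses$field_side_cm == 5])
    m10 <- mean(ses$reading[ses$field_side_cm == 10])
    m5 / m10
  })
  # 7 detectors x 2 measurements: sigma/sqrt(n) * sqrt(2) ~ 0.038%
  se_expect <- 0.001 * sqrt(2 / 14)
  expect_gt(stats::sd(ratios) / mean(ratios), 0.5 * se_expect)
  expect_lt(stats::sd(ratios) / mean(ratios), 1.6 * se_expect)
})

test_that("spectra: constant soft fraction gives identical spectra, kB = 0 is unquenched", {
  tab <- default_stopping_power()
  sp <- make_spectra(c(1, 5, 20), soft_fraction = function(s) rep(0.06, length(s)),
                     n_particles = 50, rng_seed = 3)
  expect_identical(sp[[1]]$particles, sp[[3]]$particles)
  expect_equal(kioq_ratio(sp[[1]], sp[[2]], tab), 1)
  sp2 <- make_spectra(c(0.6, 10, 40), n_particles = 50, rng_seed = 3)
  expect_equal(kioq_ratio(sp2[[1]], sp2[[2]], tab, birks_params(kB = 0)), 1)
  # decreasing soft fraction violates the monotonicity contract
  expect_error(make_spectra(c(1, 10), soft_fraction = function(s) 0.1 - 0.001 * s),
               "monotone")
})

test_that("soft-enriched spectra move the quenching ratio by 0.1-0.5%", {
  tab <- default_stopping_power()
  sp <- make_spectra(c(0.6, 10, 40), n_particles = 200, rng_seed = 11)
  dev_small <- abs(kioq_ratio(sp[[1]], sp[[2]], tab) - 1)
  dev_large <- abs(kioq_ratio(sp[[3]], sp[[2]], tab) - 1)
  expect_gt(dev_small, 0.001)
  expect_lt(dev_small, 0.005)
  expect_gt(dev_large, 0.001)
  expect_lt(dev_large, 0.005)
})

test_that("msr-prime records invert exactly and B recovery is unbiased", {
  rec <- make_msr_prime_records(-0.005)
  expect_equal(suppressMessages(fit_B(rec))$B, -0.005, tolerance = 1e-12)
  set.seed(7)
  Bs <- replicate(100, {
    r <- make_msr_prime_records(0.0035, noise_rel = 0.001,
                                rng_seed = sample.int(2^30, 1))
    suppressMessages(fit_B(r))$B
  })
  se <- stats::sd(Bs) / sqrt(length(Bs))
  expect_lt(abs(mean(Bs) - 0.0035), 3 * se + 1e-5)
})

test_that("session and profile round-trip through their CSV formats", {
  d <- withr::local_tempdir()
  sp <- field_spec(1.5)
  pr <- make_profile(sp, "crossline", n_points = 21)
  f <- file.path(d, "p.csv")
  write_profile_csv(pr, f)
  expect_equal(read_profile_csv(f), pr)
  ses <- make_session(lapply(c(2, 10), field_spec),
                      session_spec("ic", "IC", n_repeats = 2))
  f2 <- file.path(d, "s.csv")
  write_session_csv(ses, f2)
  back <- read_session_csv(f2)
  expect_equal(back$reading, ses$reading)
  f3 <- file.path(d, "spec.yaml")
  write_field_spec_yaml(sp, f3)
  expect_equal(read_field_spec_yaml(f3), sp)
})
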