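test_that("type I corrections multiply per detector class", {
  expect_equal(apply_type1(100, type1_factors(), "IC")$M, 100)
  r <- apply_type1(1, type1_factors(kpol = 1.02, kion = 0.999), "IC")
  expect_equal(r$M, 1.02 * 0.999)
  expect_equal(r$M, 1.01898)
  # class contract: kion is not in the scintillator correction equation
  expect_error(apply_type1(1, type1_factors(kion = 1.01), "PSD"),
               "not in the PSD")
  expect_error(apply_type1(1, type1_factors(kpol = 1.01), "SS"),
               "not in the SS")
  expect_error(type1_factors(kpol = -1), "positive")
  expect_error(type1_factors(kfoo = 1.1), "unknown")
})

test_that("corrected-reading ratios track which factor ratios are unity", {
  clin <- apply_type1(0.7, type1_factors(kpol = 1.02, kion = 0.999), "IC")
  msr <- apply_type1(1.0, type1_factors(kpol = 1.01, kion = 0.999), "IC")
  rr <- corrected_ratio(clin, msr)
  expect_equal(as.numeric(rr), 0.7 * 1.02 * 0.999 / (1.01 * 0.999))
  expect_true("kion" %in% attr(rr, "unity_factors"))
  expect_false("kpol" %in% attr(rr, "unity_factors"))
  # toggling a unity-declared factor in both readings leaves the ratio fixed
  clin2 <- apply_type1(0.7, type1_factors(kpol = 1.02, kion = 0.999,
                                          kstem = 1.05), "IC")
  msr2 <- apply_type1(1.0, type1_factors(kpol = 1.01, kion = 0.999,
                                         kstem = 1.05), "IC")
  expect_equal(as.numeric(corrected_ratio(clin2, msr2)), as.numeric(rr))
})

test_that("polarity factor from bias pairs", {
  expect_equal(kpol_from_bias_pair(1, 1, 1), 1)
  expect_equal(kpol_from_bias_pair(1.00, 1.04, 1.00), 1.02)
  expect_error(kpol_from_bias_pair(1, 1, 0), "nonzero")
  expect_warning(kpol_from_bias_pair(-1, 1.04, -1), "swapped")
  # recovery from a synthetic session with an injected curve
  sides <- c(0.6, 2, 10)
  kp_true <- function(S) 1 + 0.01 * exp(-S)
  ses <- make_session(lapply(sides, field_spec),
                      session_spec("ic", "IC", true_kpol = kp_true,
                                   reading_noise_rel = 0, n_repeats = 1))
  plus <- ses$reading[ses$polarity == "+"]
  minus <- ses$reading[ses$polarity == "-"]
  expect_equal(kpol_from_bias_pair(plus, minus, plus), kp_true(sides),
               tolerance = 1e-12)
})

test_that("Boag two-voltage correction for pulsed beams", {
  expect_equal(boag_two_voltage(1, 1, 300, 150), 1)
  expect_equal(boag_two_voltage(1.002, 1, 300, 150), 1 / 0.998)
  expect_error(boag_two_voltage(2, 1, 300, 150), "singular")
  expect_error(boag_two_voltage(1, 1, 150, 300), "V_H > V_L")
  # synthetic general-recombination loss f(V) = 1 - c/V: the two-voltage
  # estimate recovers 1/f at the operating bias to linearization order
  cc <- 0.6
  f <- function(V) 1 - cc / V
  k <- boag_two_voltage(f(300), f(150), 300, 150)
  expect_equal(k, 1 / f(300), tolerance = 1e-5)
})

test_that("dose-per-pulse recombination ratio model", {
  expect_equal(kion_ratio(0.1 * 0.5, 1), 1)
  expect_equal(kion_ratio(0.0035, 0.5), 0.998254, tolerance = 1e-6)
  expect_error(kion_ratio(0.2, 0.5), "< 0.1")
  expect_error(kion_ratio(0.01, -1), "positive")
  # monotone in the ratio, crossing one exactly at ratio one
  r <- seq(0.3, 1.5, by = 0.05)
  k <- kion_ratio(0.005, r)
  expect_true(all(diff(k) > 0))
  expect_equal(kion_ratio(0.005, 1), 1)
  k2 <- kion_ratio(-0.005, r)
  expect_true(all(diff(k2) < 0))
  # solid-state-scale B values keep the ratios within 0.3% of unity over
  # the output-factor range of reading ratios
  rr <- true_output_factor(c(0.6, 1, 2)) / true_output_factor(10)
  for (B in c(0.0035, -0.001, 0.0004, -0.005, -0.003))
    expect_lt(max(abs(kion_ratio(B, rr) - 1)), 0.003)
})

test_that("scaled reference side keeps the field size at the detector plane", {
  expect_equal(scale_msr_prime(10, 90), 10)
  expect_equal(scale_msr_prime(10, 80), 100 / 9, tolerance = 1e-12)
  expect_equal(round(scale_msr_prime(10, 80), 2), 11.11)
  expect_equal(round(scale_msr_prime(10, 110), 2), 8.33)
  expect_error(scale_msr_prime(10, -5), "positive")
})

test_that("chamber-to-solid-state recombination transfer", {
  expect_equal(transfer_kion_to_SS(1.2, 1.2, 0.998, 1.001), 0.998 * 1.001)
  expect_equal(transfer_kion_to_SS(1.2, 1.2, 1, 1), 1)
  expect_error(transfer_kion_to_SS(1, 0, 1), "nonzero")
  # with an injected B the transferred ratios refit to the same B
  B <- -0.004
  rec <- make_msr_prime_records(B)
  ss_raw <- rec$ratio / rec$kion_ratio      # SS reading carries the loss
  ic_raw <- rec$ratio                        # idealized chamber after kpol
  k_ss <- transfer_kion_to_SS(ic_raw, ss_raw, rep(1, 4), rep(1, 4))
  rec2 <- data.frame(SSD_cm = rec$SSD_cm, ratio = rec$ratio,
                     kion_ratio = k_ss)
  expect_equal(suppressMessages(fit_B(rec2))$B, B, tolerance = 1e-10)
})

test_that("B calibration inverts the model and reports the SSD spread", {
  rec <- make_msr_prime_records(-0.005)
  fb <- suppressMessages(fit_B(rec))
  expect_equal(fb$B, -0.005, tolerance = 1e-12)
  expect_equal(nrow(fb$per_SSD), 3)          # SSD 90 record has ratio ~1... excluded
  expect_error(fit_B(rec[1, ]), "at least 2")
  # uncertainty is the max spread over the mean
  rec3 <- data.frame(SSD_cm = c(80, 100, 110), ratio = c(1.2, 0.9, 0.7),
                     kion_ratio = kion_ratio(0.003, c(1.2, 0.9, 0.7)) *
                       c(1.001, 1, 0.999))
  fb3 <- fit_B(rec3)
  expect_equal(fb3$B_uncertainty,
               abs(diff(range(fb3$per_SSD$B)) / fb3$B))
  # synthetic chamber-like detectors land in the printed magnitude range
  for (B in c(0.0005, 0.002, 0.0045)) {
    r <- make_msr_prime_records(B, noise_rel = 2e-4, rng_seed = 123)
    expect_gt(abs(suppressMessages(fit_B(r))$B), 0.0004)
    expect_lt(abs(suppressMessages(fit_B(r))$B), 0.005)
  }
})
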