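# step-like table: high stopping power below ~0.1 MeV, low above, so the
# two spectral components see effectively constant-L values
step_table <- function(L_soft = 8, L_hard = 1.9) {
  stopping_power_table(c(0.001, 0.099, 0.101, 10),
                       c(L_soft, L_soft, L_hard, L_hard))
}

test_that("light yield reduces to deposited energy without quenching", {
  tab <- step_table()
  qi <- quenching_input(1, data.frame(Emin_MeV = c(0.1, 0.2),
                                      Emax_MeV = c(0.6, 0.4)))
  expect_equal(light_yield(qi, tab, birks_params(kB = 0)), 0.5 + 0.2)
})

test_that("constant stopping power has the closed-form quenched yield", {
  tab <- stopping_power_table(c(0.001, 10), c(2, 2))
  qi <- quenching_input(1, data.frame(Emin_MeV = 0.1, Emax_MeV = 0.6))
  expect_equal(light_yield(qi, tab, birks_params(kB = 0.019)),
               0.5 / (1 + 0.019 * 2), tolerance = 1e-7)
  expect_equal(round(light_yield(qi, tab, birks_params(kB = 0.019)), 5),
               0.48170)
})

test_that("piecewise-linear table matches a fine-grid brute-force integral", {
  E <- c(0.001, 0.01, 0.1, 1, 10)
  L <- c(120, 22, 4.2, 1.9, 1.95)
  tab <- stopping_power_table(E, L)
  qi <- quenching_input(1, data.frame(Emin_MeV = 0.004, Emax_MeV = 2))
  got <- light_yield(qi, tab, birks_params(kB = 0.019))
  # brute force: trapezoid on a dense log grid through the interpolator
  eg <- exp(seq(log(0.004), log(2), length.out = 60001))
  fv <- 1 / (1 + 0.019 * tab$fun(eg))
  brute <- sum((fv[-1] + fv[-length(fv)]) / 2 * diff(eg))
  expect_equal(got, brute, tolerance = 1e-6)
})

test_that("table contracts: positivity, monotone grid, range errors", {
  expect_error(stopping_power_table(c(1, 1), c(2, 2)), "increasing")
  expect_error(stopping_power_table(c(1, 2), c(-1, 2)), "positive")
  tab <- step_table()
  qi <- quenching_input(1, data.frame(Emin_MeV = 0.5, Emax_MeV = 20))
  expect_error(light_yield(qi, tab), "range")
  expect_error(quenching_input(1, data.frame(Emin_MeV = 0.5,
                                             Emax_MeV = 0.4)),
               "Emax > Emin")
  expect_error(quenching_input(1, data.frame(Emin_MeV = 1e-5,
                                             Emax_MeV = 0.4)),
               "cutoff")
})

test_that("quenching only reduces light and cancels the efficiency scale", {
  tab <- default_stopping_power()
  set.seed(31)
  for (i in 1:10) {
    emin <- stats::runif(3, 0.002, 0.5)
    qi <- quenching_input(1, data.frame(Emin_MeV = emin,
                                        Emax_MeV = emin +
                                          stats::runif(3, 0.01, 2)))
    ideal <- light_yield(qi, tab, birks_params(kB = 0))
    quench <- light_yield(qi, tab, birks_params(kB = 0.019))
    expect_lt(quench, ideal)
    expect_gt(quench, 0)
    # A rescales both yields identically
    expect_equal(light_yield(qi, tab, birks_params(kB = 0.019, A = 7)),
                 7 * quench, tolerance = 1e-10)
  }
})

test_that("kioq is one for identical spectra or kB = 0, and is order invariant", {
  tab <- default_stopping_power()
  qi <- quenching_input(1, data.frame(Emin_MeV = c(0.01, 0.2),
                                      Emax_MeV = c(0.05, 1.0)))
  expect_identical(kioq_ratio(qi, qi, tab), 1)
  expect_identical(kioq_ratio(qi, qi, tab, birks_params(kB = 0)), 1)
  qs <- make_spectra(c(1, 10), n_particles = 30, rng_seed = 5)
  expect_equal(kioq_ratio(qs[[1]], qs[[2]], tab,
                          birks_params(kB = 0)), 1)
  # particle order does not matter
  shuf <- qi
  shuf$particles <- shuf$particles[2:1, ]
  expect_equal(kioq_ratio(shuf, qi, tab), 1, tolerance = 1e-12)
})

test_that("two-component constant-L spectra match the hand-derived ratio", {
  tab <- step_table(8, 1.9)
  kB <- 0.019
  # msr: soft energy 0.05 MeV in (0.01, 0.06), hard 1.0 MeV in (0.2, 1.2)
  msr <- quenching_input(10, data.frame(Emin_MeV = c(0.01, 0.2),
                                        Emax_MeV = c(0.06, 1.2)))
  # clin carries 10% more soft energy via the weight
  clin <- quenching_input(1, data.frame(Emin_MeV = c(0.01, 0.2),
                                        Emax_MeV = c(0.06, 1.2),
                                        weight = c(1.1, 1)))
  hand <- function(ws) {
    ideal <- ws * 0.05 + 1
    quench <- ws * 0.05 / (1 + kB * 8) + 1 / (1 + kB * 1.9)
    ideal / quench
  }
  expect_equal(kioq_ratio(clin, msr, tab, birks_params(kB)),
               hand(1.1) / hand(1), tolerance = 1e-6)
})

test_that("kB sensitivity: zero spread for identical spectra, monotone deviation", {
  tab <- default_stopping_power()
  qi <- quenching_input(1, data.frame(Emin_MeV = 0.01, Emax_MeV = 0.5))
  s0 <- kB_sensitivity(qi, qi, tab)
  expect_equal(attr(s0, "max_spread"), 0)
  sp <- make_spectra(c(40, 10), n_particles = 100, rng_seed = 8)
  devs <- vapply(c(0.005, 0.01, 0.019, 0.03), function(kb)
    abs(kioq_ratio(sp[[1]], sp[[2]], tab, birks_params(kb)) - 1),
    numeric(1))
  expect_true(all(diff(devs) > 0))
  s1 <- kB_sensitivity(sp[[1]], sp[[2]], tab)
  expect_gt(attr(s1, "max_spread"), 0)
  expect_equal(nrow(s1), 2)
})
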