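quad_model <- function() {
  dose_profile_model(a = c(1, 0, -0.01), b = c(1, 0, -0.01),
                     valid_halfwidth = 20)
}

test_that("footprint heights follow the closed-form chord lengths", {
  g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
  expect_equal(footprint_height(g, 0.2, -0.3), 1 / (pi * 0.25))
  expect_equal(footprint_height(g, 0.6, 0), 0)
  gs <- sensitive_volume("sphere", 1)
  expect_equal(footprint_height(gs, 0.3, 0.2),
               2 * sqrt(1 - 0.09 - 0.04) / (4 / 3 * pi))
  gp <- sensitive_volume("cylinder", 0.5, 2, "perpendicular")
  expect_equal(footprint_height(gp, 0.2, 0.7),
               2 * sqrt(0.25 - 0.04) / (pi * 0.25 * 2))
  expect_equal(footprint_height(gp, 0.2, 1.2), 0)
  expect_error(sensitive_volume("cube", 1), "arg")
})

test_that("footprint moments integrate to one and match hand-derived values", {
  for (g in list(sensitive_volume("sphere", 1.3),
                 sensitive_volume("cylinder", 0.5, 1, "parallel"),
                 sensitive_volume("cylinder", 0.5, 2, "perpendicular"),
                 sensitive_volume("cylinder_hemisphere_tip", 1, 2.6,
                                  "parallel"),
                 sensitive_volume("cylinder_hemisphere_tip", 1, 2.6,
                                  "perpendicular"))) {
    mu <- geometry_moments(g)
    expect_equal(mu[1, 1], 1, tolerance = 1e-8)
    cf <- closed_form_moments(g)
    if (!is.null(cf)) {
      expect_equal(mu[3, 1], cf$mu20, tolerance = 1e-7)
      expect_equal(mu[1, 3], cf$mu02, tolerance = 1e-7)
      if (is.finite(cf$mu22))
        expect_equal(mu[3, 3], cf$mu22, tolerance = 1e-6)
    }
  }
})

test_that("measured signal matches disk and ball moment closed forms", {
  m <- quad_model()
  g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
  r <- 0.5
  expect_equal(measured_signal(m, g, 0, 0),
               1 - 2 * 0.01 * r^2 / 4 + 1e-4 * r^4 / 24, tolerance = 1e-9)
  gs <- sensitive_volume("sphere", 1)
  expect_equal(measured_signal(m, gs, 0, 0),
               (1 - 0.01 / 5)^2 + 1e-4 * (1 / 35 - 1 / 25), tolerance = 1e-8)
  # uniform dose gives the dose back for every geometry (normalization)
  mu_flat <- dose_profile_model(a = c(2.5, 0, 0), b = c(1, 0, 0),
                                valid_halfwidth = 20)
  for (g2 in list(g, gs,
                  sensitive_volume("cylinder_hemisphere_tip", 1, 2.6,
                                   "perpendicular")))
    expect_equal(measured_signal(mu_flat, g2, 1, -2), 2.5, tolerance = 1e-7)
})

test_that("numeric convolution matches brute-force grid quadrature", {
  # small randomized version of the oracle-equivalence property; the
  # full-size sweep lives in the acceptance suite
  set.seed(99)
  geoms <- list(sensitive_volume("sphere", 1.2),
                sensitive_volume("cylinder", 0.6, 1.5, "perpendicular"),
                sensitive_volume("cylinder_hemisphere_tip", 0.8, 2,
                                 "parallel"))
  geoms <- lapply(geoms, smallfieldOF:::.with_moments)
  for (i in 1:5) {
    m <- random_concave_model()
    for (g in geoms) {
      x0 <- stats::runif(1, -0.3, 0.3); y0 <- stats::runif(1, -0.3, 0.3)
      expect_equal(measured_signal(m, g, x0, y0, warn = FALSE),
                   brute_force_signal(m, g, x0, y0),
                   tolerance = 1e-5)
    }
  }
})

test_that("expected signal reduces to the measured signal and point closed form", {
  m <- quad_model()
  g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
  w0 <- position_window(0)
  expect_equal(expected_signal(m, g, w0, 0.2, 0.1, warn = FALSE),
               measured_signal(m, g, 0.2, 0.1, warn = FALSE))
  # point detector: <M>/M = product of (1 + c2 w^2 / (3 c0)) factors
  pt <- sensitive_volume("cylinder", 1e-7, 1e-7, "parallel")
  w <- position_window(0.5, 0.3)
  ratio <- expected_signal(m, pt, w, 0, 0) / measured_signal(m, pt, 0, 0)
  expect_equal(ratio, (1 - 0.01 * 0.25 / 3) * (1 - 0.01 * 0.09 / 3),
               tolerance = 1e-9)
  # uniform dose: expectation equals the dose for any window
  mu_flat <- dose_profile_model(a = c(3, 0, 0), b = c(1, 0, 0),
                                valid_halfwidth = 20)
  expect_equal(expected_signal(mu_flat, g, position_window(1), 0, 0),
               3, tolerance = 1e-7)
})

test_that("expected signal matches the window-averaged brute-force kernel", {
  set.seed(17)
  m <- random_concave_model()
  g <- smallfieldOF:::.with_moments(sensitive_volume("sphere", 1))
  w <- position_window(0.4, 0.2)
  expect_equal(expected_signal(m, g, w, 0.1, -0.1, warn = FALSE),
               brute_force_expected(m, g, w, 0.1, -0.1),
               tolerance = 1e-4)
})

test_that("signal variance has the exact limits and linear closed form", {
  m <- quad_model()
  g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
  mu_flat <- dose_profile_model(a = c(2, 0, 0), b = c(1, 0, 0),
                                valid_halfwidth = 20)
  expect_equal(signal_variance(mu_flat, g, position_window(0.5), 0, 0), 0)
  expect_equal(signal_variance(m, g, position_window(0), 0, 0), 0)
  lin <- dose_profile_model(a = c(1, 0.05, -1e-12), b = c(1, 0, -1e-12),
                            valid_halfwidth = 50)
  pt <- sensitive_volume("cylinder", 1e-7, 1e-7, "parallel")
  expect_equal(signal_variance(lin, pt, position_window(0.1, 0), 0, 0),
               0.05^2 * 0.1^2 / 3, tolerance = 1e-6)
})

test_that("kpos and kvol behave as corrections at a concave maximum", {
  m <- quad_model()
  g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
  expect_equal(as.numeric(kpos(m, g, position_window(0))), 1)
  pt <- sensitive_volume("cylinder", 1e-7, 1e-7, "parallel")
  k <- kpos(m, pt, position_window(0.1))
  expect_equal(as.numeric(k), 1 / (1 - 0.01 * 0.01 / 3)^2, tolerance = 1e-9)
  expect_equal(round(as.numeric(k), 3), 1)
  expect_gte(attr(k, "spread"), 0)
  # kvol limits and the worked disk value
  expect_equal(kvol(m, pt), 1, tolerance = 1e-9)
  expect_equal(kvol(m, g), 1 / measured_signal(m, g, 0, 0))
  expect_equal(kvol(m, g), 1.001251, tolerance = 1e-6)
})

test_that("kvol grows with radius and kpos with window width", {
  m <- quad_model()
  kv <- vapply(c(0.2, 0.5, 1, 1.5), function(r)
    kvol(m, sensitive_volume("sphere", r)), numeric(1))
  expect_true(all(diff(kv) > 0))
  g <- sensitive_volume("sphere", 0.5)
  kp <- vapply(c(0, 0.1, 0.3, 0.6), function(w)
    as.numeric(kpos(m, g, position_window(w))), numeric(1))
  expect_true(all(diff(kp) > 0))
})

test_that("preset geometries reproduce the detector dimensions", {
  expect_equal(detector_preset("IBA RAZNC")$volume_mm3, 4 / 3 * pi,
               tolerance = 1e-12)
  razc <- detector_preset("IBA RAZC", "perpendicular")
  expect_equal(razc$volume_mm3, pi * 2.6 + 2 / 3 * pi, tolerance = 1e-12)
  expect_equal(detector_preset("PRB-0002")$volume_mm3, pi * 0.25,
               tolerance = 1e-12)
  expect_error(detector_preset("nope"), "unknown")
  expect_length(detector_preset_names(), 6)
})
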