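# Independent oracles used across the suite.

# Brute-force midpoint quadrature of the measurement-signal convolution on
# an n x n grid, in sine-transformed coordinates so the sqrt-type footprint
# edges are regular.  Independent of the package's moment-contraction path.
brute_force_signal <- function(model, geom, x0, y0, n = 400L) {
  ext <- smallfieldOF:::.sv_extent(geom)
  ph <- seq(-pi / 2, pi / 2, length.out = n + 1L)
  ph <- (ph[-1L] + ph[-(n + 1L)]) / 2
  dph <- pi / n
  u <- ext[1] * sin(ph)
  yl <- vapply(u, function(x) smallfieldOF:::.sv_ylim(geom, x), numeric(2))
  mid <- (yl[1, ] + yl[2, ]) / 2
  hw <- (yl[2, ] - yl[1, ]) / 2
  U <- rep(u, each = n)
  Y <- rep(mid, each = n) + rep(hw, each = n) * sin(ph)
  J <- rep(ext[1] * cos(ph) * dph, each = n) * rep(hw, each = n) *
    cos(ph) * dph
  h <- footprint_height(geom, U, Y)
  D <- dose_value(model, x0 + U, y0 + Y)
  sum(D * h * J)
}

# Window-averaged footprint kernel on the same grid: used as the
# brute-force oracle for the expected signal (the window average commutes
# onto the kernel).
brute_force_expected <- function(model, geom, window, x0, y0, n = 400L,
                                 n_win = 21L) {
  sx <- seq(-window$wx, window$wx, length.out = n_win)
  sy <- seq(-window$wy, window$wy, length.out = n_win)
  tot <- 0
  for (a in sx) for (b in sy)
    tot <- tot + brute_force_signal(model, geom, x0 + a, y0 + b, n = 60L)
  tot / (n_win^2)
}

# Random concave separable quadratic model, curvature up to 0.02 per mm^2.
random_concave_model <- function() {
  dose_profile_model(
    a = c(stats::runif(1, 0.8, 1.2), stats::runif(1, -0.004, 0.004),
          -stats::runif(1, 0.001, 0.02)),
    b = c(stats::runif(1, 0.8, 1.2), stats::runif(1, -0.004, 0.004),
          -stats::runif(1, 0.001, 0.02)),
    valid_halfwidth = 30)
}

# Closed-form footprint moments (hand-derived): disk and ball second
# moments, chord-weighted cylinder, hemisphere-tipped cylinder (parallel).
closed_form_moments <- function(geom) {
  r <- geom$radius; L <- geom$length
  if (geom$shape == "sphere")
    return(list(mu20 = r^2 / 5, mu02 = r^2 / 5, mu22 = r^4 / 35))
  if (geom$shape == "cylinder" && geom$orientation == "parallel")
    return(list(mu20 = r^2 / 4, mu02 = r^2 / 4, mu22 = r^4 / 24))
  if (geom$shape == "cylinder" && geom$orientation == "perpendicular")
    return(list(mu20 = r^2 / 4, mu02 = L^2 / 12, mu22 = r^2 * L^2 / 48))
  if (geom$shape == "cylinder_hemisphere_tip" &&
      geom$orientation == "parallel") {
    V <- pi * r^2 * L + 2 / 3 * pi * r^3
    mu20 <- pi * (L * r^4 / 4 + 2 * r^5 / 15) / V
    return(list(mu20 = mu20, mu02 = mu20, mu22 = NA_real_))
  }
  NULL
}

# Dense-grid root finding of the 50% crossings of the closed-form field
# generator along one axis through the field center.
analytic_fwhm <- function(spec, axis = c("x", "y")) {
  axis <- match.arg(axis)
  off <- spec$center_offset
  f <- if (axis == "x") function(p) field_value(spec, p, off[2]) else
    function(p) field_value(spec, off[1], p)
  ctr <- if (axis == "x") off[1] else off[2]
  pk <- f(ctr)
  span <- spec$nominal_side * 10
  lo <- stats::uniroot(function(p) f(p) - pk / 2, c(ctr - span, ctr),
                       tol = 1e-12)$root
  hi <- stats::uniroot(function(p) f(p) - pk / 2, c(ctr, ctr + span),
                       tol = 1e-12)$root
  c(lo = lo, hi = hi, fwhm = hi - lo)
}
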