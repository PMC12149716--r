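#' Detector sensitive volume geometry
#'
#' Describes the shape, size and orientation of a detector's sensitive
#' volume.  The geometry determines the normalized height function
#' `h(x, y)` over the footprint area in the plane perpendicular to the
#' beam, which weights the dose distribution in the measurement-signal
#' convolution (see [measured_signal()]).  Supported shapes are a sphere,
#' a cylinder, and a cylinder capped by a half-sphere at one end (the
#' geometry of some micro ionization chambers).
#'
#' Orientation refers to the symmetry axis of the volume relative to the
#' beam axis: `"parallel"` (axis along the beam, footprint is a disk) or
#' `"perpendicular"` (axis along the in-line `y` direction).  For a sphere
#' the orientation is irrelevant.
#'
#' For the hemisphere-tipped cylinder the reference point (the detector
#' "position") is the midpoint of the total axial extent `length + radius`;
#' in perpendicular orientation the flat end points toward negative `y`.
#'
#' @param shape one of `"sphere"`, `"cylinder"`, `"cylinder_hemisphere_tip"`.
#' @param radius radius of the sphere / cylinder cross-section, in mm.
#' @param length cylinder length in mm (exclusive of the hemispherical tip);
#'   0 for a sphere.
#' @param orientation `"parallel"` or `"perpendicular"` symmetry axis with
#'   respect to the beam axis.
#' @return An object of class `sensitive_volume`.
#' @examples
#' sensitive_volume("cylinder", radius = 0.5, length = 1,
#'                  orientation = "perpendicular")
#' @export
sensitive_volume <- function(shape = c("sphere", "cylinder",
                                       "cylinder_hemisphere_tip"),
                             radius, length = 0,
                             orientation = c("parallel", "perpendicular")) {
  shape <- match.arg(shape)
  orientation <- match.arg(orientation)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a single positive number (mm)")
  if (!is.numeric(length) || length(length) != 1L || length < 0)
    stop("'length' must be a single non-negative number (mm)")
  if (shape == "sphere" && length > 0)
    stop("a sphere has no length; use length = 0")
  if (shape != "sphere" && length <= 0)
    stop("cylindrical shapes need a positive 'length'")
  g <- structure(list(shape = shape, radius = radius, length = length,
                      orientation = orientation),
                 class = "sensitive_volume")
  g$volume_mm3 <- .sv_volume(g)
  g
}

#' @export
print.sensitive_volume <- function(x, ...) {
  cat(sprintf("<sensitive_volume> %s, r = %g mm, L = %g mm, %s axis (V = %.4g mm^3)\n",
              x$shape, x$radius, x$length, x$orientation, x$volume_mm3))
  invisible(x)
}

.sv_volume <- function(geom) {
  r <- geom$radius; L <- geom$length
  switch(geom$shape,
    sphere = 4 / 3 * pi * r^3,
    cylinder = pi * r^2 * L,
    cylinder_hemisphere_tip = pi * r^2 * L + 2 / 3 * pi * r^3)
}

#' Geometry presets for the studied small-field detectors
#'
#' Sensitive-volume geometries (shape, radius, length) of the six detector
#' models handled by the package: two micro ionization chambers with
#' spherical volumes (IBA Razor Nano, SI Exradin A26), a hemisphere-tipped
#' cylindrical micro chamber (IBA Razor), a diode and a synthetic diamond
#' with thin cylindrical volumes (IBA Razor diode, PTW 60019), and a
#' cylindrical plastic scintillator probe (PRB-0002).
#'
#' @param name detector model key: one of `"IBA RAZNC"`, `"IBA RAZC"`,
#'   `"SI A26"`, `"IBA RAZD"`, `"PTW 60019"`, `"PRB-0002"`.
#' @param orientation symmetry-axis orientation passed to
#'   [sensitive_volume()]; ignored for spherical volumes.
#' @return A `sensitive_volume` object.
#' @examples
#' detector_preset("PRB-0002", orientation = "perpendicular")
#' @export
detector_preset <- function(name, orientation = "parallel") {
  tab <- list(
    "IBA RAZNC" = list(shape = "sphere",                  radius = 1.0,  length = 0),
    "IBA RAZC"  = list(shape = "cylinder_hemisphere_tip", radius = 1.0,  length = 2.6),
    "SI A26"    = list(shape = "sphere",                  radius = 1.65, length = 0),
    "IBA RAZD"  = list(shape = "cylinder",                radius = 0.3,  length = 0.02),
    "PTW 60019" = list(shape = "cylinder",                radius = 1.1,  length = 0.001),
    "PRB-0002"  = list(shape = "cylinder",                radius = 0.5,  length = 1.0))
  if (!name %in% names(tab))
    stop("unknown detector preset: ", name,
         " (available: ", paste(names(tab), collapse = ", "), ")")
  p <- tab[[name]]
  if (p$shape == "sphere") orientation <- "parallel"
  sensitive_volume(p$shape, p$radius, p$length, orientation)
}

#' Names of the available detector geometry presets
#' @return Character vector of preset keys for [detector_preset()].
#' @export
detector_preset_names <- function() {
  c("IBA RAZNC", "IBA RAZC", "SI A26", "IBA RAZD", "PTW 60019", "PRB-0002")
}

#' Normalized height of the sensitive volume over its footprint
#'
#' The height function `h(x, y)` gives the extent of the sensitive volume
#' along the beam axis at offset `(x, y)` from the detector reference
#' point, normalized so that it integrates to one over the footprint.
#' A uniform unit dose therefore produces a unit measurement signal.
#'
#' @param geom a [sensitive_volume()].
#' @param x,y offsets from the detector center, in mm (vectorized,
#'   recycled to common length).
#' @return Numeric vector of heights (per mm^2); zero outside the footprint.
#' @examples
#' g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
#' footprint_height(g, 0, 0)  # 1 / (pi * 0.5^2)
#' @export
footprint_height <- function(geom, x, y) {
  stopifnot(inherits(geom, "sensitive_volume"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- geom$radius; L <- geom$length; V <- geom$volume_mm3
  h <- numeric(n)
  if (geom$shape == "sphere") {
    s2 <- r^2 - x^2 - y^2
    inside <- s2 > 0
    h[inside] <- 2 * sqrt(s2[inside]) / V
  } else if (geom$shape == "cylinder") {
    if (geom$orientation == "parallel") {
      inside <- x^2 + y^2 <= r^2
      h[inside] <- 1 / (pi * r^2)          # height L cancels: L / (pi r^2 L)
    } else {                               # axis along y
      inside <- abs(x) < r & abs(y) <= L / 2
      h[inside] <- 2 * sqrt(r^2 - x[inside]^2) / V
    }
  } else {                                 # cylinder_hemisphere_tip
    if (geom$orientation == "parallel") {
      rho2 <- x^2 + y^2
      inside <- rho2 <= r^2
      h[inside] <- (L + sqrt(pmax(r^2 - rho2[inside], 0))) / V
    } else {
      # axis along y; total extent L + r centered at 0, flat end at -(L+r)/2
      half <- (L + r) / 2
      cyl <- abs(x) < r & y >= -half & y <= half - r
      h[cyl] <- 2 * sqrt(r^2 - x[cyl]^2) / V
      s <- y - (half - r)                  # axial distance into the tip
      tip2 <- r^2 - x^2 - s^2
      tip <- s > 0 & tip2 > 0
      h[tip] <- 2 * sqrt(tip2[tip]) / V
    }
  }
  h
}

# Exact y-limits of the footprint at offset x (the support of h(x, .)),
# so the quadrature integrand is smooth inside the integration range.
.sv_ylim <- function(geom, x) {
  r <- geom$radius; L <- geom$length
  if (geom$shape == "sphere" ||
      (geom$shape == "cylinder" && geom$orientation == "parallel") ||
      (geom$shape == "cylinder_hemisphere_tip" &&
       geom$orientation == "parallel")) {
    w <- sqrt(max(r^2 - x^2, 0))
    return(c(-w, w))
  }
  if (geom$shape == "cylinder")                   # perpendicular
    return(c(-L / 2, L / 2))
  half <- (L + r) / 2                             # hemi tip, perpendicular
  c(-half, half - r + sqrt(max(r^2 - x^2, 0)))
}

# Footprint bounding half-widths (x then y), used by integration and grids.
.sv_extent <- function(geom) {
  r <- geom$radius; L <- geom$length
  switch(geom$shape,
    sphere = c(r, r),
    cylinder = if (geom$orientation == "parallel") c(r, r) else c(r, L / 2),
    cylinder_hemisphere_tip =
      if (geom$orientation == "parallel") c(r, r) else c(r, (L + r) / 2))
}

#' Footprint moments of a sensitive volume
#'
#' Computes the moments `mu_ij = integral of x^i y^j h(x, y) dx dy` of the
#' normalized height function for `i, j = 0..2`, by nested adaptive
#' quadrature.  Because the dose model is a separable quadratic, the
#' measurement-signal convolution is an exact contraction of these moments
#' (see [measured_signal()]); the moments are cached on the geometry's
#' first use.
#'
#' @param geom a [sensitive_volume()].
#' @param rel_tol relative integration tolerance.
#' @return A 3x3 matrix `M` with `M[i + 1, j + 1] = mu_ij`.
#' @export
geometry_moments <- function(geom, rel_tol = 1e-8) {
  stopifnot(inherits(geom, "sensitive_volume"))
  key <- "smallfieldOF_moments"
  cached <- attr(geom, key)
  if (!is.null(cached)) return(cached)
  ext <- .sv_extent(geom)
  mu <- matrix(NA_real_, 3, 3,
               dimnames = list(paste0("x", 0:2), paste0("y", 0:2)))
  for (i in 0:2) for (j in 0:2) {
    inner <- function(xv) {
      vapply(xv, function(x0) {
        yl <- .sv_ylim(geom, x0)
        if (yl[2] <= yl[1]) return(0)
        f <- function(yv) yv^j * footprint_height(geom, rep(x0, length(yv)), yv)
        stats::integrate(f, yl[1], yl[2], rel.tol = rel_tol,
                         abs.tol = rel_tol * 1e-3,
                         subdivisions = 400L)$value
      }, numeric(1))
    }
    g <- function(xv) xv^i * inner(xv)
    mu[i + 1, j + 1] <- stats::integrate(g, -ext[1], ext[1],
                                         rel.tol = rel_tol,
                                         abs.tol = rel_tol * 1e-3,
                                         subdivisions = 400L)$value
  }
  mu
}

# Attach cached moments to a geometry (returns the modified object).
.with_moments <- function(geom, rel_tol = 1e-8) {
  if (is.null(attr(geom, "smallfieldOF_moments")))
    attr(geom, "smallfieldOF_moments") <- geometry_moments(geom, rel_tol)
  geom
}

# Taylor vector of a 1-D quadratic p(c0,c1,c2) about x0: value, slope, c2.
.quad_taylor <- function(co, x0) {
  c(co[1] + co[2] * x0 + co[3] * x0^2, co[2] + 2 * co[3] * x0, co[3])
}

#' Measurement signal of a finite detector in a quadratic dose field
#'
#' Convolves the separable quadratic dose model with the detector
#' footprint: `M(x0, y0) = integral of D(x, y) h(x - x0, y - y0) dx dy`.
#' For a quadratic model this reduces exactly to a contraction of the
#' footprint moments (computed by adaptive quadrature) with the Taylor
#' coefficients of the axis polynomials about `(x0, y0)`.
#'
#' @param model a [dose_profile_model()].
#' @param geom a [sensitive_volume()].
#' @param x0,y0 detector center position in mm.
#' @param warn warn when the footprint extends beyond the model's valid
#'   region (extrapolation of the quadratic).
#' @return Signal in the dose units of the model.
#' @examples
#' m <- dose_profile_model(a = c(1, 0, -0.01), b = c(1, 0, -0.01),
#'                         valid_halfwidth = 10)
#' g <- sensitive_volume("cylinder", 0.5, 1, "parallel")
#' measured_signal(m, g, 0, 0)   # about 0.99875
#' @export
measured_signal <- function(model, geom, x0 = NULL, y0 = NULL, warn = TRUE) {
  stopifnot(inherits(model, "dose_profile_model"))
  if (is.null(x0)) x0 <- model$xmax
  if (is.null(y0)) y0 <- model$ymax
  geom <- .with_moments(geom)
  ext <- .sv_extent(geom)
  if (warn &&
      (abs(x0) + ext[1] > model$valid_halfwidth ||
       abs(y0) + ext[2] > model$valid_halfwidth))
    warning("detector footprint extends beyond the model's valid region")
  mu <- attr(geom, "smallfieldOF_moments")
  Fv <- .quad_taylor(model$a, x0)
  Gv <- .quad_taylor(model$b, y0)
  drop(Fv %*% mu %*% Gv)
}

#' Square positioning-uncertainty window
#'
#' Half-widths of the two-dimensional square probability density that
#' describes the residual detector positioning error.
#'
#' @param wx,wy half-widths in mm (non-negative).
#' @return An object of class `position_window`.
#' @export
position_window <- function(wx, wy = wx) {
  if (wx < 0 || wy < 0) stop("window half-widths must be >= 0")
  structure(list(wx = wx, wy = wy), class = "position_window")
}

# Even moments (orders 0, 2, 4) of U(-w, w); odd moments vanish.
.window_moments <- function(w) c(1, 0, w^2 / 3, 0, w^4 / 5)

# E[p(x0+s) q(x0+s)] for two 1-D polynomials (coef vectors over s) under
# the square window moments m (orders 0..4).
.poly_cross_moment <- function(p, q, m) {
  conv <- rep(0, length(p) + length(q) - 1)
  for (i in seq_along(p)) for (j in seq_along(q))
    conv[i + j - 1] <- conv[i + j - 1] + p[i] * q[j]
  sum(conv * m[seq_along(conv)])
}

#' Expected measurement signal under positioning uncertainty
#'
#' Expectation of [measured_signal()] over a square positioning window
#' centered at `(x0, y0)`: the average of `M(x0 + s, y0 + t)` with `s`, `t`
#' uniform on the window half-widths.  Reduces to [measured_signal()] for a
#' zero-width window.
#'
#' @inheritParams measured_signal
#' @param window a [position_window()].
#' @return Expected signal.
#' @export
expected_signal <- function(model, geom, window, x0 = NULL, y0 = NULL,
                            warn = TRUE) {
  stopifnot(inherits(model, "dose_profile_model"),
            inherits(window, "position_window"))
  if (is.null(x0)) x0 <- model$xmax
  if (is.null(y0)) y0 <- model$ymax
  geom <- .with_moments(geom)
  ext <- .sv_extent(geom)
  if (warn &&
      (abs(x0) + ext[1] + window$wx > model$valid_halfwidth ||
       abs(y0) + ext[2] + window$wy > model$valid_halfwidth))
    warning("window-enlarged footprint extends beyond the model's valid region")
  mu <- attr(geom, "smallfieldOF_moments")
  Fv <- .quad_taylor(model$a, x0)
  Gv <- .quad_taylor(model$b, y0)
  # window averaging shifts only the zeroth Taylor component
  Fbar <- c(Fv[1] + model$a[3] * window$wx^2 / 3, Fv[2], Fv[3])
  Gbar <- c(Gv[1] + model$b[3] * window$wy^2 / 3, Gv[2], Gv[3])
  drop(Fbar %*% mu %*% Gbar)
}

#' Variance of the measurement signal under positioning uncertainty
#'
#' Analytic variance `Var(M) = <M^2> - <M>^2` of the measurement signal
#' when the detector position is drawn from the square window.  Computed
#' from exact polynomial moments of the window (orders up to 4), and
#' clipped at zero against roundoff.
#'
#' @inheritParams expected_signal
#' @return Variance of the signal (signal units squared); zero for a
#'   zero-width window or a uniform dose.
#' @export
signal_variance <- function(model, geom, window, x0 = NULL, y0 = NULL) {
  stopifnot(inherits(model, "dose_profile_model"),
            inherits(window, "position_window"))
  if (is.null(x0)) x0 <- model$xmax
  if (is.null(y0)) y0 <- model$ymax
  geom <- .with_moments(geom)
  mu <- attr(geom, "smallfieldOF_moments")
  Fv <- .quad_taylor(model$a, x0)
  Gv <- .quad_taylor(model$b, y0)
  # polynomials in the window offsets s (x) and t (y)
  Fp <- list(c(Fv[1], Fv[2], Fv[3]), c(Fv[2], 2 * Fv[3]), Fv[3])
  Gp <- list(c(Gv[1], Gv[2], Gv[3]), c(Gv[2], 2 * Gv[3]), Gv[3])
  mx <- .window_moments(window$wx)
  my <- .window_moments(window$wy)
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    A[i, k] <- .poly_cross_moment(Fp[[i]], Fp[[k]], mx)
    B[i, k] <- .poly_cross_moment(Gp[[i]], Gp[[k]], my)
  }
  m2 <- sum(A * (mu %*% B %*% t(mu)))
  ef <- vapply(1:3, function(i) .poly_cross_moment(Fp[[i]], 1, mx), numeric(1))
  eg <- vapply(1:3, function(j) .poly_cross_moment(Gp[[j]], 1, my), numeric(1))
  m1 <- drop(ef %*% mu %*% eg)
  max(m2 - m1^2, 0)
}

#' Positional-uncertainty correction factor
#'
#' `kpos = M(xmax, ymax) / <M(xmax, ymax)>`: the signal at the dose maximum
#' divided by its expectation under the square positioning window.  At a
#' concave maximum any positioning error reduces the expected signal, so
#' `kpos >= 1`.  The relative statistical spread of the signal (from
#' [signal_variance()]) is attached as attribute `"spread"`.
#'
#' @inheritParams expected_signal
#' @return `kpos` (dimensionless) with attribute `spread` (relative sd of
#'   the signal under the window).
#' @examples
#' m <- dose_profile_model(a = c(1, 0, -0.01), b = c(1, 0, -0.01),
#'                         valid_halfwidth = 10)
#' g <- detector_preset("PRB-0002")
#' kpos(m, g, position_window(0.1))
#' @export
kpos <- function(model, geom, window) {
  M <- measured_signal(model, geom, warn = FALSE)
  Mbar <- expected_signal(model, geom, window, warn = FALSE)
  v <- signal_variance(model, geom, window)
  structure(M / Mbar, spread = sqrt(v) / Mbar)
}

#' Volume-averaging correction factor
#'
#' `kvol = D(xmax, ymax) / M(xmax, ymax)`: the point dose at the profile
#' maximum divided by the detector-footprint-averaged signal.  Greater
#' than or equal to one for a model concave at its maximum, and tends to
#' one as the sensitive volume shrinks to a point.
#'
#' @inheritParams measured_signal
#' @return `kvol` (dimensionless).
#' @export
kvol <- function(model, geom) {
  D <- dose_value(model, model$xmax, model$ymax)
  D / measured_signal(model, geom, warn = FALSE)
}
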