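#' Separable quadratic dose model near the beam axis
#'
#' Relative two-dimensional dose in the plane perpendicular to the beam,
#' `D(x, y) = f(x) g(y)` with `f` and `g` second-order polynomials.  The
#' approximation is valid near the central axis of a small field, inside
#' `valid_halfwidth` of the maximum; it is the common currency between the
#' profile-fitting and detector-response routines.
#'
#' @param a,b numeric length-3 coefficient vectors `(c0, c1, c2)` of
#'   `f(x)` and `g(y)` with positions in mm (`c1` per mm, `c2` per mm^2).
#' @param valid_halfwidth half-width (mm) of the region where the
#'   quadratic is trusted.
#' @param rms residual RMS of the fit that produced the model (optional).
#' @return Object of class `dose_profile_model` with elements `a`, `b`,
#'   `xmax`, `ymax`, `valid_halfwidth`, `rms`, `concave`.
#' @export
dose_profile_model <- function(a, b, valid_halfwidth, rms = NA_real_) {
  stopifnot(length(a) == 3, length(b) == 3, valid_halfwidth > 0)
  concave <- c(x = a[3] < 0 || (a[2] == 0 && a[3] == 0),
               y = b[3] < 0 || (b[2] == 0 && b[3] == 0))
  xmax <- if (a[3] < 0) -a[2] / (2 * a[3]) else 0
  ymax <- if (b[3] < 0) -b[2] / (2 * b[3]) else 0
  m <- structure(list(a = as.numeric(a), b = as.numeric(b),
                      xmax = xmax, ymax = ymax,
                      valid_halfwidth = valid_halfwidth,
                      rms = rms, concave = concave),
                 class = "dose_profile_model")
  if (dose_value(m, xmax, ymax) <= 0)
    stop("dose model is not positive at its maximum")
  m
}

#' @export
print.dose_profile_model <- function(x, ...) {
  cat(sprintf("<dose_profile_model> f: (%.5g, %.5g, %.5g)  g: (%.5g, %.5g, %.5g)\n",
              x$a[1], x$a[2], x$a[3], x$b[1], x$b[2], x$b[3]))
  cat(sprintf("  max at (%.4g, %.4g) mm, valid |x|,|y| <= %.3g mm",
              x$xmax, x$ymax, x$valid_halfwidth))
  if (is.finite(x$rms)) cat(sprintf(", fit RMS %.3g", x$rms))
  cat("\n")
  invisible(x)
}

#' Evaluate a separable quadratic dose model
#'
#' @param model a [dose_profile_model()].
#' @param x,y positions in mm (vectorized).
#' @return `D(x, y) = f(x) g(y)`.
#' @export
dose_value <- function(model, x, y) {
  stopifnot(inherits(model, "dose_profile_model"))
  (model$a[1] + model$a[2] * x + model$a[3] * x^2) *
    (model$b[1] + model$b[2] * y + model$b[3] * y^2)
}

# FWHM of a sampled profile by linear interpolation at half the maximum.
.profile_fwhm <- function(position, value) {
  i <- which.max(value)
  half <- value[i] / 2
  left <- right <- NA_real_
  lo <- which(value[seq_len(i)] < half)
  if (length(lo)) {
    j <- max(lo)
    left <- position[j] + (half - value[j]) *
      (position[j + 1] - position[j]) / (value[j + 1] - value[j])
  }
  hi <- which(value[i:length(value)] < half)
  if (length(hi)) {
    j <- i + min(hi) - 1L
    right <- position[j - 1] + (half - value[j - 1]) *
      (position[j] - position[j - 1]) / (value[j] - value[j - 1])
  }
  c(left = left, right = right, fwhm = right - left)
}

#' Fit the separable quadratic dose model to orthogonal profiles
#'
#' Least-squares fit of second-order polynomials to the core of a
#' cross-line (`x`) and an in-line (`y`) relative dose profile.  The
#' in-line polynomial is normalized to `g(0) = 1` so that the cross-line
#' polynomial carries the dose scale (the product model is gauge
#' invariant for the ratio-type correction factors computed from it).
#'
#' @param cross_profile,inline_profile data frames with columns
#'   `position_mm` and `value`.
#' @param fit_halfwidth half-width (mm) of the fit window around the
#'   profile center.  Default: 15 percent of the profile FWHM (a window
#'   of 30 percent of the FWHM), where the quadratic approximation holds.
#' @return A [dose_profile_model()] carrying the residual RMS.  If a
#'   fitted quadratic is convex over a peaked profile a warning is issued
#'   and the `concave` flag is set accordingly.
#' @export
fit_quadratic_profile <- function(cross_profile, inline_profile,
                                  fit_halfwidth = NULL) {
  fit_axis <- function(p, name) {
    stopifnot(all(c("position_mm", "value") %in% names(p)))
    fw <- .profile_fwhm(p$position_mm, p$value)
    # center on the midpoint of the 50% crossings: on a flat-topped
    # profile the arg-max is a tie that lands on one shoulder
    ctr <- if (all(is.finite(fw[c("left", "right")])))
      (fw[["left"]] + fw[["right"]]) / 2 else
      p$position_mm[which.max(p$value)]
    hw <- fit_halfwidth
    if (is.null(hw)) {
      if (!is.finite(fw[["fwhm"]]))
        stop("cannot estimate FWHM to set the fit window; ",
             "supply 'fit_halfwidth'")
      hw <- 0.15 * fw[["fwhm"]]
    }
    keep <- abs(p$position_mm - ctr) <= hw
    if (sum(keep) < 5)
      stop("need >= 5 points per axis inside the fit window (", name, ")")
    x <- p$position_mm[keep]; v <- p$value[keep]
    fit <- stats::lm(v ~ x + I(x^2))
    co <- unname(stats::coef(fit))
    co[is.na(co)] <- 0
    if (co[3] > 0)
      warning("non-concave fit on the ", name,
              " axis: fitted quadratic is convex over a peaked profile")
    list(co = co, rms = sqrt(mean(stats::resid(fit)^2)), hw = hw, ctr = ctr)
  }
  fx <- fit_axis(cross_profile, "cross-line")
  fy <- fit_axis(inline_profile, "in-line")
  b <- fy$co / fy$co[1]                    # gauge: g(0) = 1
  dose_profile_model(a = fx$co, b = b,
                     valid_halfwidth = min(fx$hw, fy$hw),
                     rms = sqrt((fx$rms^2 + fy$rms^2) / 2))
}

#' Field center and FWHM by the 11-points penumbra-sampling technique
#'
#' Step-and-shoot determination of the field center and the full width at
#' half maximum on both axes from eleven point readings: per axis, two
#' readings on each penumbra near the 30 and 70 percent levels, a fifth
#' reading at the estimated axis center used as normalization, and a final
#' reading at the two-dimensional center.  Linear interpolation on each
#' edge (the penumbra slopes are taken as linear between the sampled
#' levels) locates the 50-percent crossings of the normalization reading;
#' the center is their midpoint and the FWHM their distance.
#'
#' @param profile_sampler function `(x, y) -> reading` returning one
#'   reading at any position in mm (a synthetic field or an interpolator
#'   over measured data); each call represents one measurement.
#' @param initial_center length-2 numeric, initial visual centering (mm).
#' @param nominal_side nominal field side in cm (sets the search range for
#'   the penumbra samples).
#' @param levels the two penumbra target levels as fractions of the
#'   central reading (defaults 0.3 and 0.7).
#' @return Object of class `centering_result`: `center` (mm), `FSx`, `FSy`
#'   (cm), `normalization` (the 11th reading), and `samples`, a data frame
#'   of the eleven `(axis, position_mm, reading)` values.
#' @export
eleven_point_centering <- function(profile_sampler, initial_center = c(0, 0),
                                   nominal_side, levels = c(0.3, 0.7)) {
  stopifnot(is.function(profile_sampler), length(initial_center) == 2,
            nominal_side > 0, length(levels) == 2, all(levels > 0 & levels < 1))
  levels <- sort(levels)
  side_mm <- nominal_side * 10
  samples <- data.frame(axis = character(), position_mm = numeric(),
                        reading = numeric())
  axis_pass <- function(center, fixed, axis) {
    at <- if (axis == "x") function(p) profile_sampler(p, fixed) else
                           function(p) profile_sampler(fixed, p)
    ref <- at(center)                       # scouting reading, not stored
    # locate approximate 30/70% positions by a coarse outward scan
    span <- side_mm / 2 + max(6, side_mm / 2)
    grid <- seq(center - span, center + span, length.out = 241L)
    vals <- vapply(grid, at, numeric(1))
    find_pos <- function(level, side) {
      target <- level * ref
      idx <- if (side == "right") which(grid >= center) else rev(which(grid <= center))
      below <- which(vals[idx] < target)
      if (!length(below)) stop("bracketing failure: cannot find the ",
                               round(level * 100), "% level on the ", side,
                               " edge")
      j2 <- idx[min(below)]; j1 <- idx[min(below) - 1L]
      grid[j1] + (target - vals[j1]) * (grid[j2] - grid[j1]) /
        (vals[j2] - vals[j1])
    }
    pos <- c(find_pos(levels[1], "left"),  find_pos(levels[2], "left"),
             find_pos(levels[2], "right"), find_pos(levels[1], "right"))
    rd <- vapply(pos, at, numeric(1))
    edge_cross <- function(p1, r1, p2, r2, target) {
      if ((r1 - target) * (r2 - target) > 0)
        stop("bracketing failure: penumbra samples do not bracket the 50% level")
      p1 + (target - r1) * (p2 - p1) / (r2 - r1)
    }
    # preliminary center at 50% of the scouting reading
    c0 <- mean(c(edge_cross(pos[1], rd[1], pos[2], rd[2], 0.5 * ref),
                 edge_cross(pos[3], rd[3], pos[4], rd[4], 0.5 * ref)))
    norm <- at(c0)                          # 5th reading: normalization
    xl <- edge_cross(pos[1], rd[1], pos[2], rd[2], 0.5 * norm)
    xr <- edge_cross(pos[3], rd[3], pos[4], rd[4], 0.5 * norm)
    ctr <- (xl + xr) / 2
    if (ctr < min(pos) || ctr > max(pos))
      stop("center estimate fell outside the penumbra sampling positions")
    list(center = ctr, fwhm = xr - xl,
         samples = data.frame(axis = axis,
                              position_mm = c(pos, c0),
                              reading = c(rd, norm)))
  }
  px <- axis_pass(initial_center[1], initial_center[2], "x")
  py <- axis_pass(initial_center[2], px$center, "y")
  norm11 <- profile_sampler(px$center, py$center)
  samples <- rbind(px$samples, py$samples,
                   data.frame(axis = "center", position_mm = NA_real_,
                              reading = norm11))
  structure(list(center = c(x = px$center, y = py$center),
                 FSx = px$fwhm / 10, FSy = py$fwhm / 10,
                 normalization = norm11, samples = samples),
            class = "centering_result")
}

#' @export
print.centering_result <- function(x, ...) {
  cat(sprintf("<centering_result> center (%.3f, %.3f) mm, FSx %.3f cm, FSy %.3f cm\n",
              x$center[1], x$center[2], x$FSx, x$FSy))
  invisible(x)
}

#' Equivalent square field size and its uncertainty
#'
#' `Sclin = sqrt(FSx * FSy)`, the geometric mean of the cross-line and
#' in-line FWHMs, with first-order uncertainty propagation:
#' `sigma_Sclin = (1/2) sqrt((FSy/FSx) sigma_FSx^2 + (FSx/FSy) sigma_FSy^2)`.
#'
#' @param FSx,FSy measured field widths (FWHM) in cm.
#' @param sigma_FSx,sigma_FSy their standard uncertainties in mm.
#' @return Object of class `field_size` with `FSx`, `FSy`, `Sclin` (cm)
#'   and `sigma_FSx`, `sigma_FSy`, `sigma_Sclin` (mm).
#' @examples
#' equivalent_square(1, 1, 0.02, 0.05)$sigma_Sclin  # 0.027 mm
#' @export
equivalent_square <- function(FSx, FSy, sigma_FSx = 0, sigma_FSy = 0) {
  if (any(c(FSx, FSy) <= 0)) stop("field sizes must be positive")
  if (any(c(sigma_FSx, sigma_FSy) < 0)) stop("uncertainties must be >= 0")
  Sclin <- sqrt(FSx * FSy)
  sigma <- 0.5 * sqrt((FSy / FSx) * sigma_FSx^2 + (FSx / FSy) * sigma_FSy^2)
  structure(list(FSx = FSx, FSy = FSy, Sclin = Sclin,
                 sigma_FSx = sigma_FSx, sigma_FSy = sigma_FSy,
                 sigma_Sclin = sigma),
            class = "field_size")
}

#' @export
print.field_size <- function(x, ...) {
  cat(sprintf("<field_size> FSx %.4g cm, FSy %.4g cm, Sclin %.4g cm (sigma %.3g mm)\n",
              x$FSx, x$FSy, x$Sclin, x$sigma_Sclin))
  invisible(x)
}
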