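#' Sigmoid-saturation output-factor model
#'
#' Parametrization of the corrected reading ratio versus equivalent
#' square field size `S` (cm): a saturating sigmoid term plus an
#' exponential phantom-scatter buildup,
#' `P_inf * S^n / (l^n + S^n) + S_inf * (1 - exp(-b S))`, normalized so
#' the value at the 10 cm reference side is one.
#'
#' @param S field sides in cm.
#' @param params list or named vector with elements `l`, `n`, `b`,
#'   `Pinf`, `Sinf` (all positive).
#' @return Model values, equal to 1 at `S = 10` by construction.
#' @export
of_model <- function(S, params) {
  p <- as.list(params)
  raw <- function(s) p$Pinf * s^p$n / (p$l^p$n + s^p$n) +
    p$Sinf * (1 - exp(-p$b * s))
  raw(S) / raw(10)
}

#' Sigmoid-plus-linear output-correction-factor model
#'
#' Parametrization of the output correction factor versus equivalent
#' square field size,
#' `kQ(S) = (1 + q4 exp(-(10 - q1)/q2)) / (1 + q4 exp(-(S - q1)/q2))
#'  + q3 (S - 10)`, which equals one at the 10 cm reference side for any
#' parameter values.
#'
#' @param S field sides in cm.
#' @param params list or named vector with elements `q1`, `q2`, `q3`,
#'   `q4` (`q2 > 0`).
#' @return Model values.
#' @export
kq_model <- function(S, params) {
  p <- as.list(params)
  (1 + p$q4 * exp(-(10 - p$q1) / p$q2)) /
    (1 + p$q4 * exp(-(S - p$q1) / p$q2)) + p$q3 * (S - 10)
}

#' Bounded weighted nonlinear least squares
#'
#' Fits `y = model(S, params)` by bounded nonlinear least squares
#' (Levenberg-Marquardt with box constraints), weighting residuals by the
#' supplied per-point uncertainties.  Non-convergence is flagged in the
#' result, never silent.
#'
#' @param model function `(S, params) -> values` with `params` a named
#'   list.
#' @param S,y data (at least as many points as parameters).
#' @param sigma per-point standard uncertainties; `NULL` for unweighted.
#' @param start named list of starting values.
#' @param lower,upper named bounds (same names as `start`).
#' @param max_iter iteration cap.
#' @return Object of class `bounded_fit`: `params` (named list),
#'   `covariance`, `residuals`, `converged`, `message`, `bounds`, and a
#'   `predict(S)` function.
#' @export
fit_bounded <- function(model, S, y, sigma = NULL, start, lower, upper,
                        max_iter = 200) {
  stopifnot(length(S) == length(y))
  if (length(unique(S)) < length(start))
    stop("rank deficiency: fewer distinct field sizes than parameters")
  if (length(y) < length(start))
    stop("need at least as many points as parameters")
  w <- if (is.null(sigma)) rep(1, length(y)) else {
    stopifnot(length(sigma) == length(y), all(sigma > 0))
    1 / sigma
  }
  nm <- names(start)
  resid_fun <- function(p) {
    pl <- as.list(stats::setNames(p, nm))
    w * (y - model(S, pl))
  }
  fit <- minpack.lm::nls.lm(par = unlist(start), lower = unlist(lower)[nm],
                            upper = unlist(upper)[nm], fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  converged <- fit$info %in% 1:4
  p <- as.list(fit$par)
  dof <- max(length(y) - length(start), 1)
  s2 <- fit$deviance / dof
  # invert J'J with diagonal scaling: the parameter scales differ by
  # orders of magnitude and a raw solve() is numerically singular
  d <- sqrt(diag(fit$hessian))
  d[!is.finite(d) | d == 0] <- 1
  cov <- tryCatch(s2 * solve(fit$hessian / outer(d, d)) / outer(d, d),
                  error = function(e)
                    matrix(NA_real_, length(start), length(start)))
  dimnames(cov) <- list(nm, nm)
  structure(list(params = p, covariance = cov,
                 residuals = y - model(S, p),
                 fitted = model(S, p),
                 deviance = fit$deviance,
                 converged = converged, message = fit$message,
                 bounds = list(lower = lower, upper = upper),
                 predict = function(Snew) model(Snew, p)),
            class = "bounded_fit")
}

#' @export
print.bounded_fit <- function(x, ...) {
  cat("<bounded_fit>", if (x$converged) "converged" else
    paste("NOT converged:", x$message), "\n")
  print(unlist(x$params))
  cat(sprintf("residual RMS %.3g\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

# default bounds for the two curve models (the fit is bounded but the
# reference does not state the bounds; these keep the curves physical)
.of_bounds <- function() list(
  start = list(l = 1, n = 1.5, b = 0.1, Pinf = 1, Sinf = 0.2),
  lower = list(l = 1e-3, n = 0.1, b = 1e-4, Pinf = 1e-3, Sinf = 1e-6),
  upper = list(l = 50, n = 10, b = 5, Pinf = 10, Sinf = 10))

.kq_bounds <- function() list(
  start = list(q1 = 1, q2 = 2, q3 = 0, q4 = 0.1),
  lower = list(q1 = -20, q2 = 1e-3, q3 = -0.05, q4 = -10),
  upper = list(q1 = 20, q2 = 100, q3 = 0.05, q4 = 10))

#' Fit the output-factor curve to reading-ratio data
#'
#' @param S,y,sigma equivalent square sides (cm), corrected reading
#'   ratios, and optional per-point uncertainties.
#' @param start,lower,upper optional overrides of the default starting
#'   values and bounds.
#' @return A [fit_bounded()] result for [of_model()].
#' @export
fit_of_curve <- function(S, y, sigma = NULL, start = NULL, lower = NULL,
                         upper = NULL) {
  d <- .of_bounds()
  # data-driven start: sigmoid scale from the data maximum, half-saturation
  # side from interpolation; the sigmoid surface has local minima, so the
  # static default is kept as a second start and the better fit wins
  half_S <- tryCatch(stats::approx(y / max(y), S, xout = 0.5,
                                   ties = "ordered")$y,
                     error = function(e) NA_real_)
  dd <- list(l = if (is.finite(half_S)) max(half_S, 0.05) else 1,
             n = 1.3, b = 0.1, Pinf = max(y), Sinf = 0.15 * max(y))
  starts <- if (is.null(start)) list(dd, d$start) else
    list(utils::modifyList(d$start, as.list(start)))
  .fit_multistart(of_model, S, y, sigma, starts,
                  lower = utils::modifyList(d$lower, as.list(lower %||% list())),
                  upper = utils::modifyList(d$upper, as.list(upper %||% list())))
}

#' Fit the output-correction-factor curve
#'
#' @inheritParams fit_of_curve
#' @return A [fit_bounded()] result for [kq_model()].
#' @export
fit_kq_curve <- function(S, y, sigma = NULL, start = NULL, lower = NULL,
                         upper = NULL) {
  d <- .kq_bounds()
  starts <- if (is.null(start))
    list(d$start,
         list(q1 = 0.5, q2 = 1.5, q3 = 0, q4 = -0.05),
         list(q1 = 2, q2 = 3, q3 = 0, q4 = 0.5)) else
    list(utils::modifyList(d$start, as.list(start)))
  .fit_multistart(kq_model, S, y, sigma, starts,
                  lower = utils::modifyList(d$lower, as.list(lower %||% list())),
                  upper = utils::modifyList(d$upper, as.list(upper %||% list())))
}

# run fit_bounded from several starting points, keep the lowest deviance
.fit_multistart <- function(model, S, y, sigma, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    f <- tryCatch(fit_bounded(model, S, y, sigma, start = st,
                              lower = lower, upper = upper),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || (f$converged && !best$converged) ||
        (f$converged == best$converged && f$deviance < best$deviance))
      best <- f
  }
  if (is.null(best)) stop("all starting points failed")
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted quadratic interpolation of reference correction factors
#'
#' Fits a second-degree polynomial in the logarithm of the field side to
#' the reference detector's output correction factors, used only to
#' interpolate them at arbitrary field sizes.  The log abscissa matches
#' the roughly log-uniform spacing of measured field sides and tracks the
#' flat-then-drifting shape of near-unity correction data.  Evaluation
#' outside the fitted range sets an extrapolation flag on the returned
#' values.
#'
#' @param S_values,kQ_values field sides (cm) and correction factors.
#' @param sigma optional per-point uncertainties (weights `1/sigma^2`).
#' @return Object of class `kq_polynomial`: `coefficients` (intercept,
#'   linear, quadratic in `log(S)`), `range`, and a `predict(S)` function
#'   returning values with a logical attribute `"extrapolated"`.
#' @export
fit_reference_kq_polynomial <- function(S_values, kQ_values, sigma = NULL) {
  stopifnot(length(S_values) == length(kQ_values), length(S_values) >= 3,
            all(S_values > 0))
  w <- if (is.null(sigma)) NULL else 1 / sigma^2
  x <- log(S_values)
  fit <- stats::lm(kQ_values ~ x + I(x^2), weights = w)
  co <- unname(stats::coef(fit))
  rng <- range(S_values)
  predict_fun <- function(S) {
    lx <- log(S)
    out <- co[1] + co[2] * lx + co[3] * lx^2
    extra <- S < rng[1] | S > rng[2]
    if (any(extra))
      warning("extrapolating the reference polynomial outside [",
              rng[1], ", ", rng[2], "] cm")
    attr(out, "extrapolated") <- extra
    out
  }
  structure(list(coefficients = co, range = rng, predict = predict_fun),
            class = "kq_polynomial")
}
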