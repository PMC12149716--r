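#' Combine uncertainty components in quadrature
#'
#' Root-sum-square of relative uncertainty components, the standard k = 1
#' combination for independent contributions.
#'
#' @param components numeric vector of relative uncertainties in percent
#'   (all >= 0); `NA` components (not-applicable entries of a budget) are
#'   dropped.
#' @return Combined uncertainty in percent.
#' @examples
#' combine_quadrature(c(0.08, 0.07, 0.36, 0.2, 0.3, 0.026, 0.03))  # 0.52
#' @export
combine_quadrature <- function(components) {
  components <- components[!is.na(components)]
  if (!length(components)) stop("no uncertainty components supplied")
  if (any(components < 0)) stop("components must be >= 0")
  sqrt(sum(components^2))
}

#' Field-size contribution to a curve-derived uncertainty
#'
#' Propagates a field-size determination uncertainty through a fitted
#' curve: the relative contribution is `|dC/dS| * sigma_S / C(S)`, with
#' the derivative taken numerically at `S`.
#'
#' @param fit_curve function `S -> value` (a fitted reading-ratio or
#'   correction-factor curve).
#' @param S field side in cm.
#' @param sigma_S field-size standard uncertainty in cm.
#' @param h step for the central difference, in cm.
#' @return Relative contribution in percent.
#' @examples
#' fieldsize_contribution(function(S) 0.67 + 0.10 * (S - 0.66),
#'                        S = 0.66, sigma_S = 0.0071)   # about 0.106
#' @export
fieldsize_contribution <- function(fit_curve, S, sigma_S, h = 1e-4) {
  slope <- (fit_curve(S + h) - fit_curve(S - h)) / (2 * h)
  100 * abs(slope) * sigma_S / fit_curve(S)
}

#' Fit-uncertainty band by two-level Monte-Carlo resampling
#'
#' Repeatedly perturbs the correction-factor data and refits the curve to
#' obtain a pointwise uncertainty band.  Each iteration draws one shared
#' Gaussian deviation (the systematic part, affecting every field size
#' together) plus independent per-point Gaussian deviations (the random
#' part), adds them to the data, refits, and evaluates the curve on a
#' field-size grid; the band is the pointwise standard deviation of the
#' fitted curves.
#'
#' @param S field sides in cm.
#' @param values correction-factor (or reading-ratio) data at `S`.
#' @param sigma_random per-point random standard uncertainties (same
#'   units as `values`; scalar or vector).
#' @param sigma_systematic shared systematic standard uncertainty.
#' @param n_iter number of resampling iterations.
#' @param seed integer RNG seed.
#' @param grid evaluation grid in cm (default 0.5 to 40 cm in 0.5 mm
#'   steps).
#' @param fitter function `(S, y) -> function(grid) -> values`; defaults
#'   to the bounded sigmoid-plus-linear correction-factor fit.  Note that
#'   the default model is pinned to 1 at the 10 cm reference side, so a
#'   purely systematic shift is not representable there; use a fitter
#'   with a free scale (for example the quadratic reference polynomial)
#'   when the systematic component should move the whole curve.
#' @return Object of class `resampled_band`: data frame `band` with
#'   columns `S` and `sd`, plus `n_dropped` non-converged iterations.
#'   More than 5 percent dropped iterations is an error.
#' @export
resample_fit_uncertainty <- function(S, values, sigma_random,
                                     sigma_systematic, n_iter = 1000,
                                     seed = 20240101,
                                     grid = seq(0.5, 40, by = 0.05),
                                     fitter = NULL) {
  stopifnot(length(S) == length(values))
  sigma_random <- rep_len(sigma_random, length(values))
  if (any(sigma_random < 0) || sigma_systematic < 0)
    stop("sigmas must be >= 0")
  if (is.null(fitter))
    fitter <- function(S, y) {
      f <- fit_kq_curve(S, y)
      if (!f$converged) return(NULL)
      f$predict
    }
  set.seed(seed)
  curves <- matrix(NA_real_, n_iter, length(grid))
  dropped <- 0L
  for (i in seq_len(n_iter)) {
    shared <- stats::rnorm(1, 0, sigma_systematic)
    y <- values + shared + stats::rnorm(length(values), 0, sigma_random)
    pred <- tryCatch(suppressWarnings(fitter(S, y)),
                     error = function(e) NULL)
    if (is.null(pred)) { dropped <- dropped + 1L; next }
    curves[i, ] <- pred(grid)
  }
  if (dropped > 0.05 * n_iter)
    stop("more than 5% of resampling iterations failed to converge (",
         dropped, "/", n_iter, ")")
  sd_band <- apply(curves, 2, stats::sd, na.rm = TRUE)
  if (sigma_systematic == 0 && all(sigma_random == 0))
    sd_band[] <- 0                       # degenerate: no perturbation at all
  structure(list(band = data.frame(S = grid, sd = sd_band),
                 n_dropped = dropped, n_iter = n_iter),
            class = "resampled_band")
}

#' @export
print.resampled_band <- function(x, ...) {
  cat(sprintf("<resampled_band> %d iterations (%d dropped), band %.3g-%.3g\n",
              x$n_iter, x$n_dropped, min(x$band$sd), max(x$band$sd)))
  invisible(x)
}

#' One component of an uncertainty budget
#'
#' @param label component name.
#' @param type `"A"` (statistical) or `"B"` (systematic).
#' @param value relative uncertainty in percent (>= 0), possibly a vector
#'   over field sides.
#' @return Data frame row(s) for assembly into a budget.
#' @export
budget_component <- function(label, type = c("A", "B"), value) {
  type <- match.arg(type)
  if (any(value < 0, na.rm = TRUE)) stop("uncertainty must be >= 0")
  data.frame(label = label, type = type, value = value)
}

#' Assemble per-field-size uncertainty budgets
#'
#' Builds the combined k = 1 uncertainty of a measured field output
#' factor per field size and measurement scenario.  The combination rule
#' is: quadrature of the output-correction-factor input, the statistical
#' raw-reading component of the scenario, fixed 0.1 percent allowances
#' for the stem and the remaining influence-quantity ratios, and the
#' field-size determination term of the scenario.  The
#' `single_measurement` scenario uses one reading with one detector; the
#' `multi_detector` scenario averages several detectors with repeated
#' readings.
#'
#' @param field_sides field sides in cm (labels).
#' @param kq_u output-correction-factor uncertainty in percent (vector
#'   over field sides).
#' @param mraw_stat named list with elements `single_measurement` and
#'   `multi_detector`, each a percent vector over field sides.
#' @param fieldsize_term same structure as `mraw_stat`: the field-size
#'   determination contribution in percent.
#' @param kstem,kother fixed type B allowances in percent.
#' @param scenario which scenario to combine.
#' @return Object of class `of_budget`: the `components` table and the
#'   `combined` percent per field side (raw values; `round` to the
#'   printed 2 decimals for tabulation).
#' @export
build_budget_tables <- function(field_sides, kq_u, mraw_stat,
                                fieldsize_term, kstem = 0.1, kother = 0.1,
                                scenario = c("single_measurement",
                                             "multi_detector")) {
  scenario <- match.arg(scenario)
  n <- length(field_sides)
  if (!n) stop("empty component list: no field sides supplied")
  comp <- rbind(
    budget_component("output correction factor", "B", rep_len(kq_u, n)),
    budget_component("statistical Mraw", "A",
                     rep_len(mraw_stat[[scenario]], n)),
    budget_component("kstem", "B", rep_len(kstem, n)),
    budget_component("kother", "B", rep_len(kother, n)),
    budget_component("field size determination", "A",
                     rep_len(fieldsize_term[[scenario]], n)))
  if (!nrow(comp)) stop("empty component list")
  comp$field_side_cm <- rep(field_sides, times = 5)
  combined <- vapply(field_sides, function(s)
    combine_quadrature(comp$value[comp$field_side_cm == s]), numeric(1))
  structure(list(components = comp, scenario = scenario,
                 combined = stats::setNames(combined, format(field_sides))),
            class = "of_budget")
}

#' @export
print.of_budget <- function(x, ...) {
  cat("<of_budget> scenario:", x$scenario, "\n")
  wide <- stats::reshape(x$components, idvar = c("label", "type"),
                         timevar = "field_side_cm", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat("combined (k=1, %):\n")
  print(round(x$combined, 2))
  invisible(x)
}
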