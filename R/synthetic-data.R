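#' Synthetic square-field specification
#'
#' Describes one jaw-delimited square field for the synthetic-data
#' generator: nominal side, penumbra width of the error-function edge
#' model, and an optional offset of the field center from the nominal
#' beam axis.
#'
#' @param nominal_side field side in cm (> 0).
#' @param penumbra_sigma penumbra width parameter in mm (> 0): each edge
#'   is an erf sigmoid `erf((side/2 - x)/sigma)` of width `sigma` (the
#'   underlying Gaussian has standard deviation `sigma/sqrt(2)`).
#' @param center_offset numeric length-2, `(dx, dy)` field-center offset
#'   in mm.
#' @param msr_side side of the machine-specific reference field in cm.
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(nominal_side, penumbra_sigma = 2.75,
                       center_offset = c(0, 0), msr_side = 10) {
  if (!is.numeric(nominal_side) || nominal_side <= 0)
    stop("'nominal_side' must be positive (cm)")
  if (!is.numeric(penumbra_sigma) || penumbra_sigma <= 0)
    stop("'penumbra_sigma' must be positive (mm)")
  stopifnot(length(center_offset) == 2, msr_side > 0)
  structure(list(nominal_side = nominal_side,
                 penumbra_sigma = penumbra_sigma,
                 center_offset = as.numeric(center_offset),
                 msr_side = msr_side),
            class = "field_spec")
}

# One-axis error-function edge pair: difference of two erf sigmoids
# centered at +/- side/2 with erf width parameter sigma, unnormalized.
# erf(u) = 2 pnorm(u sqrt(2)) - 1.
.erf_axis <- function(p, side_mm, sigma, offset) {
  u <- (p - offset) * sqrt(2) / sigma
  s <- side_mm / 2 * sqrt(2) / sigma
  stats::pnorm(s - u) + stats::pnorm(s + u) - 1
}

#' Closed-form synthetic field value
#'
#' Relative dose of the error-function field model at `(x, y)`:
#' the product of two one-axis edge pairs, normalized to 1 at the field
#' center.  This is the analytic ground truth behind [make_profile()] and
#' the profile sampler used in recovery studies.
#'
#' @param spec a [field_spec()].
#' @param x,y positions in mm (vectorized).
#' @return Relative dose values.
#' @export
field_value <- function(spec, x, y = spec$center_offset[2]) {
  stopifnot(inherits(spec, "field_spec"))
  s <- spec$nominal_side * 10
  sg <- spec$penumbra_sigma
  peak <- .erf_axis(spec$center_offset[1], s, sg, spec$center_offset[1]) *
          .erf_axis(spec$center_offset[2], s, sg, spec$center_offset[2])
  .erf_axis(x, s, sg, spec$center_offset[1]) *
    .erf_axis(y, s, sg, spec$center_offset[2]) / peak
}

#' Sample a synthetic dose profile
#'
#' Samples the error-function field model along one axis through the
#' field center, normalized to 1 at its maximum, with optional i.i.d.
#' multiplicative Gaussian reading noise.
#'
#' @param spec a [field_spec()].
#' @param axis `"crossline"` (x) or `"inline"` (y).
#' @param n_points number of sample positions (>= 11).
#' @param half_range half-extent of the sampled positions in mm; default
#'   covers the field core and both penumbras.
#' @param noise_rel relative standard deviation of the reading noise.
#' @param rng_seed integer seed; `NULL` leaves the RNG state alone.
#' @return Data frame with columns `position_mm`, `value`.
#' @export
make_profile <- function(spec, axis = c("crossline", "inline"),
                         n_points = 61, half_range = NULL,
                         noise_rel = 0, rng_seed = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  axis <- match.arg(axis)
  if (n_points < 11) stop("n_points must be >= 11")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(half_range))
    half_range <- spec$nominal_side * 10 / 2 + 5 * spec$penumbra_sigma
  p <- seq(-half_range, half_range, length.out = n_points)
  v <- if (axis == "crossline") field_value(spec, p) else
    field_value(spec, spec$center_offset[1], p)
  v <- v / max(v)
  if (noise_rel > 0) v <- v * (1 + stats::rnorm(n_points, 0, noise_rel))
  data.frame(position_mm = p, value = v)
}

#' Default ground-truth output-factor curve of the generator
#'
#' The sigmoid-saturation plus exponential-buildup parametrization used by
#' the synthetic generator as the true relative reading/dose curve versus
#' field side, normalized to 1 at the reference side of 10 cm.  The
#' default parameters give a realistic 6 MV jaw-field curve (about 0.70 at
#' a 0.66 cm field).
#'
#' @param S field side in cm (vectorized).
#' @param params parameter list as in [of_model()].
#' @return Relative output at `S`.
#' @export
true_output_factor <- function(S, params = default_of_truth()) {
  of_model(S, params)
}

#' @rdname true_output_factor
#' @export
default_of_truth <- function() {
  list(l = 0.28, n = 1.3, b = 0.08, Pinf = 0.95, Sinf = 0.25)
}

#' Synthetic measurement-session specification
#'
#' Ground-truth nuisance parameters for [make_session()]: the detector
#' identity and class, the dose-per-pulse recombination parameter `B`, a
#' polarity-correction curve, the relative reading noise, and the number
#' of repeat readings.
#'
#' @param detector_id character label.
#' @param detector_class `"IC"`, `"SS"` or `"PSD"`.
#' @param true_B recombination parameter (dimensionless, |B| <= 0.02 for
#'   the generator).
#' @param true_kpol function(side_cm) -> polarity factor, or a single
#'   number used for all fields.
#' @param reading_noise_rel relative sd of each raw reading (>= 0).
#' @param n_repeats repeat readings per field and polarity (>= 1).
#' @param rng_seed integer seed.
#' @param bias_V operating bias magnitude in volts.
#' @param true_of function(S) giving the true relative output versus side.
#' @param true_kq function(S) giving the true output correction factor
#'   (clin/msr) of this detector; the generated raw response is
#'   `of(S) / kq(S)` before nuisance factors.
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(detector_id, detector_class = c("IC", "SS", "PSD"),
                         true_B = 0, true_kpol = 1,
                         reading_noise_rel = 0.001, n_repeats = 3,
                         rng_seed = 20240101, bias_V = 300,
                         true_of = true_output_factor,
                         true_kq = function(S) rep(1, length(S))) {
  detector_class <- match.arg(detector_class)
  if (abs(true_B) > 0.02)
    stop("'true_B' outside the generator's validity range [-0.02, 0.02]")
  if (reading_noise_rel < 0) stop("'reading_noise_rel' must be >= 0")
  if (n_repeats < 1) stop("'n_repeats' must be >= 1")
  kpol_fun <- if (is.function(true_kpol)) true_kpol else
    function(S) rep(true_kpol, length(S))
  structure(list(detector_id = detector_id, detector_class = detector_class,
                 true_B = true_B, true_kpol = kpol_fun,
                 reading_noise_rel = reading_noise_rel,
                 n_repeats = n_repeats, rng_seed = rng_seed,
                 bias_V = bias_V, true_of = true_of, true_kq = true_kq),
            class = "session_spec")
}

#' Generate a synthetic measurement session
#'
#' Produces raw readings for a set of square fields, injecting the
#' session's polarity factor, dose-per-pulse recombination (through the
#' linearized `1/(1 + B (1 - r))` model, solved self-consistently so that
#' the model inversion recovers the truth exactly at zero noise), the
#' detector's output correction factor, and multiplicative reading noise.
#' Ionization chambers get readings at both polarities; solid-state and
#' scintillator detectors at the operating polarity only.
#'
#' @param field_specs list of [field_spec()] objects (one must have
#'   `nominal_side == msr_side`, the reference field).
#' @param spec a [session_spec()].
#' @return Data frame with columns `detector_id`, `field_side_cm`,
#'   `SSD_cm`, `bias_V`, `polarity`, `reading`, `repeat_index`.  Ground
#'   truth is attached as attribute `"truth"`: a list with the true
#'   output factors, polarity factors, recombination factors and `B`.
#' @export
make_session <- function(field_specs, spec) {
  stopifnot(inherits(spec, "session_spec"))
  if (inherits(field_specs, "field_spec")) field_specs <- list(field_specs)
  sides <- vapply(field_specs, function(f) f$nominal_side, numeric(1))
  msr <- field_specs[[1]]$msr_side
  if (!any(abs(sides - msr) < 1e-9))
    stop("field_specs must include the reference field (side = msr_side)")
  set.seed(spec$rng_seed)
  of <- spec$true_of(sides)
  of_msr <- spec$true_of(msr)
  kq <- spec$true_kq(sides)
  kpol <- spec$true_kpol(sides)
  # response ratio after all corrections should equal (of/kq) / (of/kq)_msr
  rho <- (of / kq) / (of_msr / spec$true_kq(msr))
  # raw-reading ratio consistent with the linearized recombination model:
  # r = rho * (1 + B (1 - r))  =>  r = rho (1 + B) / (1 + rho B)
  B <- spec$true_B
  r <- rho * (1 + B) / (1 + rho * B)
  kpol_msr <- spec$true_kpol(msr)
  scale <- of_msr * kpol_msr               # sets Mraw(msr) = of(msr)
  m_op <- r * scale / kpol                 # operating-polarity raw reading
  rows <- list()
  noise <- function(n) 1 + stats::rnorm(n, 0, spec$reading_noise_rel)
  for (i in seq_along(sides)) {
    for (k in seq_len(spec$n_repeats)) {
      if (spec$detector_class == "IC") {
        m_minus <- 2 * m_op[i] * kpol[i] - m_op[i]
        rows[[length(rows) + 1L]] <- data.frame(
          detector_id = spec$detector_id, field_side_cm = sides[i],
          SSD_cm = 90, bias_V = c(spec$bias_V, -spec$bias_V),
          polarity = c("+", "-"),
          reading = c(m_op[i], m_minus) * noise(2),
          repeat_index = k)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          detector_id = spec$detector_id, field_side_cm = sides[i],
          SSD_cm = 90, bias_V = spec$bias_V, polarity = "+",
          reading = m_op[i] * noise(1), repeat_index = k)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(sides = sides, of = of / of_msr, kq = kq,
                             kpol = kpol, kion_raw_ratio = r, B = B,
                             rho = rho)
  out
}

#' Synthetic scaled-reference (msr') recombination records
#'
#' Emulates the varying-SSD experiment used to calibrate the
#' dose-per-pulse recombination parameter `B`: the reference field side is
#' rescaled with SSD to keep the field size at the detector plane
#' constant, the dose per pulse changes as the inverse-square factor, and
#' the recombination factor ratio follows the linearized model exactly
#' (plus optional noise).
#'
#' @param true_B ground-truth `B`.
#' @param SSDs source-to-surface distances in cm.
#' @param msr_side reference field side in cm.
#' @param noise_rel relative noise on the recorded ratios.
#' @param rng_seed integer seed.
#' @param detector_depth detector depth in cm (fixed at 10 in the study
#'   geometry).
#' @return Data frame with columns `SSD_cm`, `fmsr_prime_cm`, `ratio`
#'   (raw reading ratio msr'/msr), `kion_ratio`, `kpol_ratio`.
#' @export
make_msr_prime_records <- function(true_B, SSDs = c(80, 90, 100, 110),
                                   msr_side = 10, noise_rel = 0,
                                   rng_seed = 20240101,
                                   detector_depth = 10) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fprime <- vapply(SSDs, function(s) scale_msr_prime(msr_side, s,
                                                     detector_depth),
                   numeric(1))
  r <- (100 / (SSDs + detector_depth))^2   # inverse-square dose-per-pulse proxy
  kion <- 1 / (1 + true_B * (1 - r))
  n <- length(SSDs)
  if (noise_rel > 0) {
    r <- r * (1 + stats::rnorm(n, 0, noise_rel))
    kion <- kion * (1 + stats::rnorm(n, 0, noise_rel))
  }
  data.frame(SSD_cm = SSDs, fmsr_prime_cm = fprime, ratio = r,
             kion_ratio = kion, kpol_ratio = 1)
}

#' Default soft-electron energy fraction versus field side
#'
#' Fraction of the deposited energy carried by the soft (low-energy,
#' high-stopping-power) secondary-electron component, increasing with
#' field side as phantom scatter adds low-energy photons.  Drives the
#' field-size dependence of the synthetic quenching correction.
#'
#' @param side field side in cm (vectorized).
#' @return Soft energy fraction, monotone non-decreasing in `side`.
#' @export
default_soft_fraction <- function(side) {
  pmin(pmax(0.05 + 9e-4 * (side - 10), 0), 0.5)
}

#' Generate synthetic per-field energy-deposition spectra
#'
#' For each field side, draws a two-component set of per-particle energy
#' intervals: a hard component (electron energies of a few hundred keV to
#' MeV) and a soft component (tens of keV, where the stopping power and
#' hence Birks quenching are large).  The soft component's share of the
#' deposited energy follows `soft_fraction(side)`, so larger fields quench
#' more and the quenching correction ratio deviates from one by a few
#' tenths of a percent.
#'
#' @param field_sides field sides in cm.
#' @param soft_fraction function(side) -> soft energy fraction, monotone
#'   non-decreasing.
#' @param n_particles particles drawn per field.
#' @param rng_seed integer seed.
#' @return Named list of [quenching_input()] objects, one per field side.
#' @export
make_spectra <- function(field_sides, soft_fraction = default_soft_fraction,
                         n_particles = 400, rng_seed = 20240101) {
  sf <- soft_fraction(sort(field_sides))
  if (any(diff(sf) < -1e-12))
    stop("'soft_fraction' must be monotone non-decreasing with field side")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  # one shared interval template; only the component weights vary with
  # field size, so equal soft fractions give identical spectra
  e_soft_min <- stats::runif(n_particles, 0.005, 0.02)
  e_soft_len <- stats::runif(n_particles, 0.005, 0.03)
  e_hard_min <- stats::runif(n_particles, 0.1, 0.3)
  e_hard_len <- stats::runif(n_particles, 0.3, 1.2)
  out <- lapply(field_sides, function(s) {
    f <- soft_fraction(s)
    # weight the two components so the soft share of deposited energy is f
    w_soft <- f / sum(e_soft_len)
    w_hard <- (1 - f) / sum(e_hard_len)
    quenching_input(
      field_side = s,
      particles = data.frame(
        Emin_MeV = c(e_soft_min, e_hard_min),
        Emax_MeV = c(e_soft_min + e_soft_len, e_hard_min + e_hard_len),
        weight = c(rep(w_soft, n_particles), rep(w_hard, n_particles))))
  })
  names(out) <- format(field_sides)
  out
}
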