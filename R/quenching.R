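#' Per-field energy-deposition intervals for quenching calculations
#'
#' The exchange format for the Birks-law light-yield integral: the energy
#' interval `(Emin, Emax)` over which each charged particle deposits
#' energy inside the scintillator's sensitive volume, with an optional
#' multiplicity weight per particle.
#'
#' @param field_side field side in cm.
#' @param particles data frame with columns `Emin_MeV`, `Emax_MeV` and
#'   optionally `weight` (default 1).
#' @param cutoff energy cutoff `Delta` in MeV below which intervals are
#'   invalid (default 0.001, i.e. 1 keV).
#' @return Object of class `quenching_input`.
#' @export
quenching_input <- function(field_side, particles, cutoff = 0.001) {
  stopifnot(is.data.frame(particles),
            all(c("Emin_MeV", "Emax_MeV") %in% names(particles)),
            nrow(particles) >= 1, field_side > 0)
  if (is.null(particles$weight)) particles$weight <- 1
  if (any(particles$Emin_MeV < cutoff))
    stop("particle Emin below the energy cutoff (", cutoff, " MeV)")
  if (any(particles$Emax_MeV <= particles$Emin_MeV))
    stop("every interval needs Emax > Emin")
  if (any(particles$weight < 0)) stop("weights must be >= 0")
  structure(list(field_side = field_side, particles = particles,
                 cutoff = cutoff),
            class = "quenching_input")
}

#' @export
print.quenching_input <- function(x, ...) {
  cat(sprintf("<quenching_input> side %.3g cm, %d particles, E in [%.4g, %.4g] MeV\n",
              x$field_side, nrow(x$particles),
              min(x$particles$Emin_MeV), max(x$particles$Emax_MeV)))
  invisible(x)
}

#' Restricted stopping-power table
#'
#' Restricted linear electronic stopping power `L_Delta(E)` of the
#' scintillating material on a strictly increasing energy grid, with a
#' monotone-preserving log-log interpolator.
#'
#' @param energy_MeV strictly increasing energy grid in MeV.
#' @param L_MeV_per_cm strictly positive stopping powers in MeV/cm.
#' @param delta energy cutoff in MeV (default 0.001).
#' @return Object of class `stopping_power_table` with an element `fun`,
#'   the interpolator `function(E) -> L`.
#' @export
stopping_power_table <- function(energy_MeV, L_MeV_per_cm, delta = 0.001) {
  stopifnot(length(energy_MeV) == length(L_MeV_per_cm),
            length(energy_MeV) >= 2)
  if (any(diff(energy_MeV) <= 0)) stop("energy grid must be strictly increasing")
  if (any(L_MeV_per_cm <= 0)) stop("stopping powers must be positive")
  sf <- stats::splinefun(log(energy_MeV), log(L_MeV_per_cm),
                         method = "monoH.FC")
  rng <- range(energy_MeV)
  fun <- function(E) {
    if (any(E < rng[1] - 1e-12) || any(E > rng[2] + 1e-12))
      stop("energy outside the stopping-power table range [",
           rng[1], ", ", rng[2], "] MeV")
    exp(sf(log(E)))
  }
  structure(list(energy_MeV = energy_MeV, L_MeV_per_cm = L_MeV_per_cm,
                 delta = delta, fun = fun, range = rng),
            class = "stopping_power_table")
}

#' Read a stopping-power table from CSV
#'
#' @param path CSV file with columns `energy_MeV`, `L_MeV_per_cm`.
#' @param delta energy cutoff in MeV.
#' @return A [stopping_power_table()].
#' @export
read_stopping_power <- function(path, delta = 0.001) {
  d <- utils::read.csv(path)
  stopping_power_table(d$energy_MeV, d$L_MeV_per_cm, delta)
}

#' Bundled synthetic polystyrene-like stopping-power table
#'
#' Loads the restricted stopping-power table shipped with the package:
#' a synthetic, physically shaped tabulation for a polystyrene-like
#' scintillator (density 1.06 g/cm^3) over 1 keV to 10 MeV with a 1 keV
#' cutoff.  The values follow the characteristic shape of electron
#' collision stopping powers (steep low-energy rise, broad minimum near
#' 1-2 MeV) but are not a standard-reference tabulation; any table in the
#' same format can be substituted.
#'
#' @return A [stopping_power_table()].
#' @export
default_stopping_power <- function() {
  path <- system.file("extdata", "stopping_power_polystyrene_synthetic.csv",
                      package = "smallfieldOF", mustWork = TRUE)
  read_stopping_power(path)
}

#' Birks-law parameters
#'
#' @param kB quenching strength in cm/MeV (>= 0); 0.019 is a typical
#'   value for polystyrene-based scintillators, 0.01 a common sensitivity
#'   alternative.
#' @param A scintillation efficiency (arbitrary units; cancels in ratios).
#' @return Object of class `birks_params`.
#' @export
birks_params <- function(kB = 0.019, A = 1) {
  if (kB < 0) stop("kB must be >= 0")
  if (A <= 0) stop("A must be positive")
  structure(list(kB = kB, A = A), class = "birks_params")
}

#' Birks-law light yield of an energy-deposition spectrum
#'
#' Sum over particles of the quenched light-yield integral
#' `A / (1 + kB * L_Delta(E))` over each particle's energy interval,
#' evaluated by adaptive quadrature on a log-energy scale.  With `kB = 0`
#' this reduces to `A` times the total deposited energy.
#'
#' @param input a [quenching_input()].
#' @param table a [stopping_power_table()].
#' @param params a [birks_params()]; use `kB = 0` for the ideal
#'   (unquenched) yield.
#' @param rel_tol relative integration tolerance.
#' @return Light yield in units of `A` times MeV.
#' @export
light_yield <- function(input, table, params = birks_params(),
                        rel_tol = 1e-7) {
  stopifnot(inherits(input, "quenching_input"),
            inherits(table, "stopping_power_table"),
            inherits(params, "birks_params"))
  p <- input$particles
  if (any(p$Emin_MeV < table$range[1] - 1e-12) ||
      any(p$Emax_MeV > table$range[2] + 1e-12))
    stop("particle energy interval outside the stopping-power table range")
  if (params$kB == 0)
    return(params$A * sum(p$weight * (p$Emax_MeV - p$Emin_MeV)))
  per <- vapply(seq_len(nrow(p)), function(i) {
    integrand <- function(t) {                      # E = exp(t), dE = E dt
      E <- exp(t)
      E / (1 + params$kB * table$fun(E))
    }
    stats::integrate(integrand, log(p$Emin_MeV[i]), log(p$Emax_MeV[i]),
                     rel.tol = rel_tol, subdivisions = 200L)$value
  }, numeric(1))
  params$A * sum(p$weight * per)
}

#' Ionization-quenching correction factor ratio
#'
#' Ratio of the ideal to the Birks-quenched light yield, taken between a
#' clinical and the reference spectrum:
#' `kioq = [L_ideal / L_quenched]_clin / [L_ideal / L_quenched]_msr`.
#' Equal to one for identical spectra or `kB = 0`; the scintillation
#' efficiency `A` cancels.
#'
#' @param clin,msr [quenching_input()] spectra for the clinical and
#'   reference fields.
#' @param table a [stopping_power_table()].
#' @param params a [birks_params()].
#' @param rel_tol relative integration tolerance.
#' @return `kioq` (dimensionless, clin/msr convention).
#' @export
kioq_ratio <- function(clin, msr, table, params = birks_params(),
                       rel_tol = 1e-7) {
  if (params$kB == 0) return(1)
  ideal <- birks_params(0, params$A)
  rc <- light_yield(clin, table, ideal, rel_tol) /
        light_yield(clin, table, params, rel_tol)
  rm <- light_yield(msr, table, ideal, rel_tol) /
        light_yield(msr, table, params, rel_tol)
  rc / rm
}

#' Sensitivity of the quenching correction to the Birks parameter
#'
#' Evaluates [kioq_ratio()] for a set of `kB` values and reports the
#' maximal spread, to gauge how strongly the quenching correction depends
#' on the assumed quenching strength.
#'
#' @inheritParams kioq_ratio
#' @param kB_values Birks parameters to evaluate (cm/MeV).
#' @return Data frame with columns `kB`, `kioq`; the maximal absolute
#'   spread is attached as attribute `"max_spread"`.
#' @export
kB_sensitivity <- function(clin, msr, table, kB_values = c(0.019, 0.01),
                           rel_tol = 1e-7) {
  k <- vapply(kB_values, function(kb)
    kioq_ratio(clin, msr, table, birks_params(kb), rel_tol), numeric(1))
  out <- data.frame(kB = kB_values, kioq = k)
  attr(out, "max_spread") <- max(k) - min(k)
  out
}
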