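#' Read a perturbation-factor fixture
#'
#' Loads per-field-size wall and scintillator perturbation factors (and
#' optionally the Monte-Carlo dose chain columns used for verification)
#' from CSV.  Required columns: `field_side_cm`, `Pwall`, `Pwall_u`,
#' `Pscint`, `Pscint_u`; optional: `Ddet`, `Dscint`, `Dscint_w`, `Dw`.
#'
#' @param path CSV file path.
#' @return Data frame of class `perturbation_fixture`, sorted by field
#'   side.
#' @export
read_perturbation_fixture <- function(path) {
  d <- utils::read.csv(path)
  req <- c("field_side_cm", "Pwall", "Pwall_u", "Pscint", "Pscint_u")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("fixture is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$Pwall <= 0) || any(d$Pscint <= 0) || any(d$field_side_cm <= 0))
    stop("fixture values must be positive")
  d <- d[order(d$field_side_cm), , drop = FALSE]
  class(d) <- c("perturbation_fixture", "data.frame")
  d
}

#' Bundled synthetic perturbation-factor fixture
#'
#' Per-field-size `Pwall` and `Pscint` values for the scintillator probe,
#' synthetic but shaped so that the scintillator-composition perturbation
#' and the quenching correction offset each other (both within a few
#' tenths of a percent of one), as observed for well-balanced plastic
#' scintillators.
#'
#' @return A `perturbation_fixture` data frame.
#' @export
default_perturbation_fixture <- function() {
  read_perturbation_fixture(
    system.file("extdata", "perturbation_factors_synthetic.csv",
                package = "smallfieldOF", mustWork = TRUE))
}

#' Perturbation factors from the Monte-Carlo dose chain
#'
#' Reconstructs the perturbation factors from the four dose columns of a
#' fixture: `Pscint = Dscint_w / Dscint` (water-equivalent versus actual
#' scintillator composition) and `Pwall = Dscint / Ddet` (bare sensitive
#' volume versus full detector assembly).  When the point dose in water
#' `Dw` is present, the implied volume-averaging factor
#' `kvol = Dw / (Pscint Pwall Ddet)` is returned as well, closing the
#' chain `Dw = kvol Pscint Pwall Ddet`.
#'
#' @param fixture a `perturbation_fixture` with dose columns `Ddet`,
#'   `Dscint`, `Dscint_w` (and optionally `Dw`).
#' @return Data frame with `field_side_cm`, `Pwall`, `Pscint` and, when
#'   `Dw` is available, `kvol`.
#' @export
chain_from_doses <- function(fixture) {
  req <- c("Ddet", "Dscint", "Dscint_w")
  miss <- setdiff(req, names(fixture))
  if (length(miss)) stop("dose chain needs column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(field_side_cm = fixture$field_side_cm,
                    Pscint = fixture$Dscint_w / fixture$Dscint,
                    Pwall = fixture$Dscint / fixture$Ddet)
  if (!is.null(fixture$Dw))
    out$kvol <- fixture$Dw / (out$Pscint * out$Pwall * fixture$Ddet)
  out
}

#' Interpolate fixture perturbation factors at arbitrary field sides
#'
#' Linear interpolation in the logarithm of the field side, which matches
#' the roughly log-uniform spacing at which the factors are computed.
#'
#' @param fixture a `perturbation_fixture`.
#' @param side field sides in cm (within the fixture's range).
#' @return Data frame with `field_side_cm`, `Pwall`, `Pwall_u`, `Pscint`,
#'   `Pscint_u`.
#' @export
perturbation_at <- function(fixture, side) {
  rng <- range(fixture$field_side_cm)
  if (any(side < rng[1] - 1e-9) || any(side > rng[2] + 1e-9))
    stop("field side outside the fixture range [", rng[1], ", ", rng[2], "] cm")
  ip <- function(y) stats::approx(log(fixture$field_side_cm), y,
                                  xout = log(side), rule = 2)$y
  data.frame(field_side_cm = side,
             Pwall = ip(fixture$Pwall), Pwall_u = ip(fixture$Pwall_u),
             Pscint = ip(fixture$Pscint), Pscint_u = ip(fixture$Pscint_u))
}

#' Assemble the field output correction factor from its components
#'
#' Multiplies the four clin/msr component ratios of the perturbation
#' chain: `kQ = kvol * Pscint * Pwall * kioq`, where the quenching ratio
#' enters as the only type II factor.  Component standard uncertainties
#' (relative, in percent) are combined in quadrature and stored for the
#' budget module.
#'
#' @param kvol_ratio,Pscint_ratio,Pwall_ratio,kioq_ratio clin/msr
#'   component ratios (vectorized over field sizes).
#' @param u_kvol,u_Pscint,u_Pwall,u_kioq their relative uncertainties in
#'   percent (optional).
#' @param field_side_cm field sides for labelling (optional).
#' @return Data frame of class `correction_chain_result` with the four
#'   components, `kQ`, and `u_kQ` (percent, quadrature of the component
#'   uncertainties).
#' @export
assemble_kQ <- function(kvol_ratio, Pscint_ratio, Pwall_ratio, kioq_ratio,
                        u_kvol = 0, u_Pscint = 0, u_Pwall = 0, u_kioq = 0,
                        field_side_cm = NULL) {
  n <- max(length(kvol_ratio), length(Pscint_ratio), length(Pwall_ratio),
           length(kioq_ratio))
  kQ <- kvol_ratio * Pscint_ratio * Pwall_ratio * kioq_ratio
  u <- sqrt(rep_len(u_kvol, n)^2 + rep_len(u_Pscint, n)^2 +
            rep_len(u_Pwall, n)^2 + rep_len(u_kioq, n)^2)
  out <- data.frame(kvol = rep_len(kvol_ratio, n),
                    Pscint = rep_len(Pscint_ratio, n),
                    Pwall = rep_len(Pwall_ratio, n),
                    kioq = rep_len(kioq_ratio, n),
                    kQ = kQ, u_kQ = u)
  if (!is.null(field_side_cm))
    out <- cbind(field_side_cm = rep_len(field_side_cm, n), out)
  class(out) <- c("correction_chain_result", "data.frame")
  out
}

#' Field output factor from a corrected reading ratio
#'
#' `Omega = M_ratio * kQ`: the corrected clin/msr reading ratio converted
#' to a dose ratio by the detector's output correction factor.
#'
#' @param M_ratio corrected reading ratio clin/msr.
#' @param kQ output correction factor (clin/msr).
#' @param u_M,u_kQ relative uncertainties in percent (optional).
#' @return Data frame of class `output_factor_result` with `M_ratio`,
#'   `kQ`, `Omega` and `u_Omega` (percent, quadrature).
#' @export
output_factor <- function(M_ratio, kQ, u_M = 0, u_kQ = 0) {
  n <- max(length(M_ratio), length(kQ))
  out <- data.frame(M_ratio = rep_len(M_ratio, n), kQ = rep_len(kQ, n),
                    Omega = M_ratio * kQ,
                    u_Omega = sqrt(rep_len(u_M, n)^2 + rep_len(u_kQ, n)^2))
  class(out) <- c("output_factor_result", "data.frame")
  out
}

#' Transfer the output correction factor between detectors
#'
#' Given the corrected reading ratios of a characterized reference
#' detector and of a second detector measured in the same fields, the
#' second detector's output correction factor is
#' `kQ2 = (M1_ratio * kQ1) / M2_ratio` (both detectors measure the same
#' dose ratio).
#'
#' @param det1_M_ratio,det1_kQ reference detector's corrected reading
#'   ratio and output correction factor.
#' @param det2_M_ratio second detector's corrected reading ratio.
#' @return The second detector's `kQ`.
#' @export
transfer_kQ <- function(det1_M_ratio, det1_kQ, det2_M_ratio) {
  if (any(det2_M_ratio == 0)) stop("det2 reading ratio must be nonzero")
  det1_M_ratio * det1_kQ / det2_M_ratio
}
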