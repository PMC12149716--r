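#' Type I reading-correction factors
#'
#' Container for the multiplicative correction factors applied to a raw
#' reading that are independent of small beam-quality changes:
#' temperature-pressure (`kTP`), humidity (`kH`), electrometer (`kelec`),
#' polarity (`kpol`), ion recombination (`kion`), drift (`kdrift`),
#' background (`kbg`), stem (`kstem`), positioning (`kpos`), temperature
#' (`kT`, solid-state and scintillator detectors) and readout (`kread`,
#' scintillator detectors).  Factors not supplied default to one.
#'
#' @param ... named factors among `kTP, kH, kelec, kpol, kion, kdrift,
#'   kbg, kstem, kpos, kT, kread`; all must be positive.
#' @return Named numeric vector of class `type1_factors` with every slot
#'   present.
#' @export
type1_factors <- function(...) {
  slots <- c("kTP", "kH", "kelec", "kpol", "kion", "kdrift", "kbg",
             "kstem", "kpos", "kT", "kread")
  f <- stats::setNames(rep(1, length(slots)), slots)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all factors must be named")
    bad <- setdiff(names(dots), slots)
    if (length(bad)) stop("unknown correction factor(s): ",
                          paste(bad, collapse = ", "))
    vals <- unlist(dots)
    if (any(vals <= 0)) stop("correction factors must be positive")
    f[names(dots)] <- vals
  }
  structure(f, class = "type1_factors")
}

# Factors applicable per detector class (the class-specific correction
# equations); inapplicable factors must stay at 1.
.class_factors <- list(
  IC  = c("kTP", "kH", "kelec", "kpol", "kion", "kdrift", "kbg", "kstem", "kpos"),
  SS  = c("kT", "kelec", "kion", "kdrift", "kbg", "kstem", "kpos"),
  PSD = c("kT", "kread", "kdrift", "kbg", "kstem", "kpos"))

#' Apply type I corrections to a raw reading
#'
#' Multiplies a raw reading by the product of the correction factors
#' applicable to the detector class.  Supplying a non-unity factor that
#' the class's correction equation does not contain (for example `kion`
#' for a scintillator) is an error, which keeps the type I / type II
#' bookkeeping honest.
#'
#' @param Mraw raw reading (any consistent signal units).
#' @param factors a [type1_factors()] object.
#' @param detector_class `"IC"`, `"SS"` or `"PSD"`.
#' @return Object of class `corrected_reading`: list with `Mraw`,
#'   `factors`, `M` (the corrected signal) and `detector_class`.
#' @examples
#' apply_type1(100, type1_factors(kpol = 1.02, kion = 0.999), "IC")$M
#' @export
apply_type1 <- function(Mraw, factors, detector_class = c("IC", "SS", "PSD")) {
  detector_class <- match.arg(detector_class)
  stopifnot(inherits(factors, "type1_factors"))
  if (any(unclass(factors) <= 0)) stop("correction factors must be positive")
  applicable <- .class_factors[[detector_class]]
  other <- setdiff(names(unclass(factors)), applicable)
  off <- other[abs(unclass(factors)[other] - 1) > 1e-12]
  if (length(off))
    stop("factor(s) not in the ", detector_class, " correction equation: ",
         paste(off, collapse = ", "))
  M <- Mraw * prod(unclass(factors)[applicable])
  structure(list(Mraw = Mraw, factors = factors, M = M,
                 detector_class = detector_class),
            class = "corrected_reading")
}

#' @export
print.corrected_reading <- function(x, ...) {
  cat(sprintf("<corrected_reading> %s: Mraw %.6g -> M %.6g\n",
              x$detector_class, x$Mraw, x$M))
  invisible(x)
}

#' Ratio of two corrected readings
#'
#' Divides the corrected signal of a clinical-field reading by that of a
#' reference-field reading and records which factor ratios were taken as
#' unity (those equal in both readings).
#'
#' @param clin,msr [apply_type1()] results for the clinical and reference
#'   fields (same detector class).
#' @return Numeric ratio with attribute `unity_factors`, the names of the
#'   applicable factors whose clin/msr ratio is exactly one.
#' @export
corrected_ratio <- function(clin, msr) {
  stopifnot(inherits(clin, "corrected_reading"),
            inherits(msr, "corrected_reading"),
            clin$detector_class == msr$detector_class)
  applicable <- .class_factors[[clin$detector_class]]
  fr <- unclass(clin$factors)[applicable] / unclass(msr$factors)[applicable]
  structure(clin$M / msr$M, unity_factors = names(fr)[fr == 1])
}

#' Polarity correction factor from a bias-reversal pair
#'
#' `kpol = (|M+| + |M-|) / (2 |M_operating|)`: the mean of the absolute
#' readings at the two polarities divided by the absolute reading at the
#' normal operating polarity.
#'
#' @param M_plus,M_minus readings at positive and negative bias.
#' @param M_operating reading at the operating polarity (typically one of
#'   the two).
#' @return `kpol` (dimensionless).
#' @export
kpol_from_bias_pair <- function(M_plus, M_minus, M_operating) {
  if (any(M_operating == 0)) stop("operating reading must be nonzero")
  if (any(M_plus < 0 & M_minus > 0))
    warning("positive-bias reading is negative while negative-bias reading ",
            "is positive; inputs look swapped (absolute values are used)")
  (abs(M_plus) + abs(M_minus)) / (2 * abs(M_operating))
}

#' Boag two-voltage recombination correction (pulsed beams)
#'
#' `kion = (1 - VH/VL) / (MH/ML - VH/VL)` for a pulsed beam, from
#' readings at the operating (high) bias and a reduced bias.
#'
#' @param M_H,M_L readings at high and low bias.
#' @param V_H,V_L the bias magnitudes (V_H > V_L > 0).
#' @return `kion` at the operating bias `V_H`.
#' @export
boag_two_voltage <- function(M_H, M_L, V_H, V_L) {
  if (!(V_H > V_L && V_L > 0)) stop("need V_H > V_L > 0")
  if (any(M_H <= 0) || any(M_L <= 0)) stop("readings must be positive")
  vr <- V_H / V_L
  mr <- M_H / M_L
  if (any(abs(mr - vr) < 1e-12))
    stop("singular input: M_H/M_L equals V_H/V_L")
  (1 - vr) / (mr - vr)
}

#' Recombination-correction ratio from the dose-per-pulse model
#'
#' Linearized ion-recombination correction ratio between a clinical and
#' the reference field, `1 / (1 + B (1 - r))`, where `r` is the
#' polarity- and position-corrected raw reading ratio (a proxy for the
#' dose-per-pulse ratio) and `B` a detector-specific parameter calibrated
#' at reference conditions.
#'
#' @param B dimensionless recombination parameter (|B| < 0.1).
#' @param corrected_raw_ratio `(Mraw kpol kpos)` clin/msr ratio (> 0).
#' @return `kion` ratio; exactly one when the ratio is one.
#' @examples
#' kion_ratio(0.0035, 0.5)  # 0.998254
#' @export
kion_ratio <- function(B, corrected_raw_ratio) {
  if (abs(B) >= 0.1) stop("|B| must be < 0.1")
  if (any(corrected_raw_ratio <= 0)) stop("reading ratio must be positive")
  1 / (1 + B * (1 - corrected_raw_ratio))
}

#' Scaled reference field side at a shifted SSD
#'
#' Side of the modified reference field `fmsr' = fmsr * 100 / (SSD + d)`
#' that keeps the field size at the detector plane (depth `d`) constant
#' while the SSD changes, for the recombination-parameter calibration.
#'
#' @param fmsr_side reference field side in cm.
#' @param SSD source-to-surface distance in cm.
#' @param detector_depth detector depth in cm (default 10).
#' @return Scaled side `fmsr'` in cm.
#' @examples
#' scale_msr_prime(10, 80)   # 11.11 cm
#' @export
scale_msr_prime <- function(fmsr_side, SSD, detector_depth = 10) {
  if (SSD <= 0) stop("SSD must be positive")
  fmsr_side * 100 / (SSD + detector_depth)
}

#' Transfer a recombination ratio from a chamber to a solid-state detector
#'
#' Approximates the recombination-correction ratio of a solid-state
#' detector between the reference and a scaled-reference geometry from
#' simultaneous chamber measurements, assuming the beam quality at the
#' detector plane is unchanged by the SSD scaling:
#' `(kion)_SS = (raw IC ratio / raw SS ratio) * (kion kpol)_IC ratio`.
#'
#' @param ic_raw_ratio,ss_raw_ratio raw reading ratios (msr'/msr) of the
#'   chamber and the solid-state detector.
#' @param ic_kion_ratio,ic_kpol_ratio the chamber's correction ratios for
#'   the same pair of geometries.
#' @return The solid-state detector's `kion` ratio.
#' @export
transfer_kion_to_SS <- function(ic_raw_ratio, ss_raw_ratio,
                                ic_kion_ratio, ic_kpol_ratio = 1) {
  if (any(ss_raw_ratio == 0)) stop("solid-state raw ratio must be nonzero")
  (ic_raw_ratio / ss_raw_ratio) * ic_kion_ratio * ic_kpol_ratio
}

#' Calibrate the dose-per-pulse recombination parameter
#'
#' Inverts the linearized recombination model for each scaled-reference
#' record, `B = (1/kion - 1) / (1 - r)`; the reported `B` is the mean of
#' the inversions at the extreme SSDs (80 and 110 cm when present,
#' otherwise the smallest and largest SSD), and its relative uncertainty
#' is the maximal spread among all SSDs divided by the mean.  Records
#' with `r = 1` (no dose-per-pulse change) are excluded with a message.
#'
#' @param records data frame as produced by [make_msr_prime_records()]:
#'   columns `SSD_cm`, `ratio`, `kion_ratio` (and optionally
#'   `fmsr_prime_cm`, `kpol_ratio`).
#' @return Object of class `recombination_model`: list with `B`,
#'   `B_uncertainty` (relative), `per_SSD` (the per-record inversions)
#'   and the source `records`.
#' @export
fit_B <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("SSD_cm", "ratio", "kion_ratio") %in% names(records)))
  if (nrow(records) < 2) stop("need at least 2 SSD records")
  keep <- abs(records$ratio - 1) > 1e-12
  if (any(!keep))
    message("excluding ", sum(!keep), " record(s) with reading ratio = 1")
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) < 2) stop("fewer than 2 usable records after exclusion")
  Bs <- (1 / rec$kion_ratio - 1) / (1 - rec$ratio)
  lo <- if (80 %in% rec$SSD_cm) 80 else min(rec$SSD_cm)
  hi <- if (110 %in% rec$SSD_cm) 110 else max(rec$SSD_cm)
  B <- mean(c(Bs[match(lo, rec$SSD_cm)], Bs[match(hi, rec$SSD_cm)]))
  u <- abs((max(Bs) - min(Bs)) / B)
  structure(list(B = B, B_uncertainty = u,
                 per_SSD = data.frame(SSD_cm = rec$SSD_cm, B = Bs),
                 records = rec),
            class = "recombination_model")
}

#' @export
print.recombination_model <- function(x, ...) {
  cat(sprintf("<recombination_model> B = %.5g (rel. u %.3g), %d SSD records\n",
              x$B, x$B_uncertainty, nrow(x$per_SSD)))
  invisible(x)
}
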