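#' Default polarity-correction truth curve of the recovery study
#'
#' Mild field-size-dependent polarity factor used for the synthetic
#' ionization-chamber detector: close to one at mid sizes with a rise at
#' the smallest fields and a weak linear trend at large fields, the shape
#' typically seen for micro chambers.
#'
#' @param S field side in cm.
#' @return Polarity factor.
#' @export
default_kpol_truth <- function(S) {
  1 + 0.008 * exp(-S / 2) + 3e-4 * (S - 10) / 10
}

#' Default solid-state/chamber output-correction truth curve
#'
#' Injected detector response used as ground truth for the transferred
#' output correction factor of the synthetic chamber: above one at small
#' fields (volume averaging and fluence perturbation) and one at the
#' reference side.
#'
#' @param S field side in cm.
#' @return Correction factor.
#' @export
default_kq_ic_truth <- function(S) {
  kq_model(S, list(q1 = 0, q2 = 1.5, q3 = -5e-5, q4 = -0.05))
}

#' End-to-end synthetic output-factor recovery study
#'
#' Runs the whole measurement chain on synthetic data with known ground
#' truth: generates per-field profiles and centers the detector with the
#' 11-points technique; builds the scintillator's output correction
#' factor from the volume-averaging convolution (quadratic profile fits),
#' the fixture perturbation factors and the Birks quenching ratio;
#' corrects a chamber session for polarity (bias pairs) and dose-per-pulse
#' recombination (parameter calibrated from scaled-reference records);
#' and assembles field output factors and the transferred chamber
#' correction factor, comparing everything against the generator's truth.
#'
#' @param seed integer seed for every random component.
#' @param field_sides nominal sides in cm; must include the 10 cm
#'   reference.
#' @param noise_rel relative reading noise (default 0.001, i.e. 0.1
#'   percent).
#' @param n_repeats repeat readings per field.
#' @param n_profile_points points per generated scan profile.
#' @param true_B injected recombination parameter of the chamber.
#' @return Data frame of class `recovery_study` with one row per field:
#'   measured `Sclin`, corrected reading ratios, estimated and true
#'   output correction factors and output factors, recovery errors, and
#'   the combined k = 1 uncertainty `u_Omega_pct`.
#' @export
run_recovery_study <- function(seed = 20240101,
                               field_sides = c(0.6, 0.8, 1, 1.5, 2, 3, 4,
                                               5, 6, 8, 10, 30),
                               noise_rel = 0.001, n_repeats = 3,
                               n_profile_points = 201, true_B = 0.0035) {
  if (!any(field_sides == 10))
    stop("field_sides must include the 10 cm reference")
  set.seed(seed)
  geom <- .with_moments(detector_preset("PRB-0002",
                                        orientation = "perpendicular"))
  fixture <- default_perturbation_fixture()
  spectra <- make_spectra(field_sides, rng_seed = seed + 1L)
  sp_table <- default_stopping_power()
  msr_i <- which(field_sides == 10)

  # --- ground-truth correction chain for the scintillator -------------
  kvol_of_side <- function(side, noise, seed_off) {
    fs <- field_spec(side)
    cr <- make_profile(fs, "crossline", n_profile_points,
                       noise_rel = noise, rng_seed = seed_off)
    il <- make_profile(fs, "inline", n_profile_points,
                       noise_rel = noise, rng_seed = seed_off + 1L)
    # flat-core wide fields legitimately fit with a2 ~ 0 of either sign;
    # the non-concave warning is informative for users, not here
    kvol(suppressWarnings(fit_quadratic_profile(cr, il)), geom)
  }
  kvol_true <- vapply(field_sides, kvol_of_side, numeric(1),
                      noise = 0, seed_off = seed)
  pert <- perturbation_at(fixture, field_sides)
  kioq <- vapply(seq_along(field_sides), function(i)
    kioq_ratio(spectra[[i]], spectra[[msr_i]], sp_table), numeric(1))
  kq_psd_true_tab <- (kvol_true / kvol_true[msr_i]) *
    (pert$Pscint / pert$Pscint[msr_i]) * (pert$Pwall / pert$Pwall[msr_i]) *
    kioq
  kq_psd_fun <- stats::approxfun(field_sides, kq_psd_true_tab, rule = 2)
  kq_ic_fun <- default_kq_ic_truth

  # --- synthetic sessions ---------------------------------------------
  specs <- lapply(field_sides, function(s)
    field_spec(s, center_offset = stats::runif(2, -0.5, 0.5)))
  psd <- make_session(specs, session_spec(
    "PRB-demo", "PSD", reading_noise_rel = noise_rel,
    n_repeats = n_repeats, rng_seed = seed + 10L, true_kq = kq_psd_fun))
  ic <- make_session(specs, session_spec(
    "IC-demo", "IC", true_B = true_B, true_kpol = default_kpol_truth,
    reading_noise_rel = noise_rel, n_repeats = n_repeats,
    rng_seed = seed + 20L, true_kq = kq_ic_fun))

  # --- field size by 11-points centering (noisy point readings) --------
  Sclin <- vapply(seq_along(field_sides), function(i) {
    fs <- specs[[i]]
    sampler <- function(x, y)
      field_value(fs, x, y) * (1 + stats::rnorm(1, 0, noise_rel))
    ctr <- eleven_point_centering(sampler, c(0, 0), fs$nominal_side)
    equivalent_square(ctr$FSx, ctr$FSy)$Sclin
  }, numeric(1))

  # --- type I corrections ----------------------------------------------
  msr_records <- make_msr_prime_records(true_B, noise_rel = noise_rel,
                                        rng_seed = seed + 30L)
  B_hat <- fit_B(msr_records)$B
  mean_reading <- function(sess, side, pol)
    mean(sess$reading[sess$field_side_cm == side & sess$polarity == pol])
  psd_m <- vapply(field_sides, mean_reading, numeric(1), sess = psd, pol = "+")
  ic_plus <- vapply(field_sides, mean_reading, numeric(1), sess = ic, pol = "+")
  ic_minus <- vapply(field_sides, mean_reading, numeric(1), sess = ic, pol = "-")
  kpol_hat <- kpol_from_bias_pair(ic_plus, ic_minus, ic_plus)
  ic_raw_ratio <- (ic_plus * kpol_hat) / (ic_plus[msr_i] * kpol_hat[msr_i])
  kion_hat <- kion_ratio(B_hat, ic_raw_ratio)
  ic_ratio <- ic_raw_ratio * kion_hat
  psd_ratio <- psd_m / psd_m[msr_i]

  # --- estimated chain (noisy profile fits) and output factors ---------
  kvol_est <- vapply(seq_along(field_sides), function(i)
    kvol_of_side(field_sides[i], noise_rel, seed + 40L + 2L * i),
    numeric(1))
  chain <- assemble_kQ(kvol_est / kvol_est[msr_i],
                       pert$Pscint / pert$Pscint[msr_i],
                       pert$Pwall / pert$Pwall[msr_i],
                       kioq, field_side_cm = field_sides)
  omega <- output_factor(psd_ratio, chain$kQ)
  kq_ic_est <- transfer_kQ(psd_ratio, chain$kQ, ic_ratio)

  truth_of <- attr(psd, "truth")$of
  # combined k=1 budget per field: reading statistics, stem and residual
  # influence-ratio allowances, and the volume-averaging estimate
  u_mraw <- 100 * noise_rel * sqrt(2 / n_repeats)
  u_kvol <- 100 * abs(kvol_est / kvol_est[msr_i] /
                        (kvol_true / kvol_true[msr_i]) - 1)
  u_omega <- sqrt(u_mraw^2 + 0.1^2 + 0.1^2 + pmax(u_kvol, 0.01)^2)

  out <- data.frame(
    nominal_side_cm = field_sides, Sclin_cm = Sclin,
    M_psd_ratio = psd_ratio, M_ic_ratio = ic_ratio,
    kQ_psd = chain$kQ, kQ_psd_true = kq_psd_true_tab,
    kQ_ic = kq_ic_est, kQ_ic_true = kq_ic_fun(field_sides),
    Omega = omega$Omega, Omega_true = truth_of,
    u_Omega_pct = u_omega,
    z_Omega = 100 * (omega$Omega / truth_of - 1) / u_omega)
  class(out) <- c("recovery_study", "data.frame")
  attr(out, "B_hat") <- B_hat
  attr(out, "kpol_hat") <- kpol_hat
  out
}
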