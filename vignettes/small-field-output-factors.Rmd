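---
title: "Methods: small-field output factors and detector correction factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-field output factors and detector correction factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallfieldOF)
```

## The problem

In radiotherapy, the *field output factor* of a clinical field,
$\Omega = D_w^{clin} / D_w^{msr}$, is the ratio of absorbed dose to water
at the center of the field to that of the machine-specific reference
field (here a 10 × 10 cm² field).  For broad beams a detector reading
ratio approximates $\Omega$ directly, but for fields of a few millimetres
to a few centimetres the conversion from reading to dose becomes
field-size dependent: the detector averages dose over a finite sensitive
volume, perturbs the local charged-particle fluence, and may respond
differently to the changing secondary-electron spectrum.  The TRS-483
formalism absorbs all of this into a detector-specific *output correction
factor*,

$$\Omega = \frac{M^{clin}}{M^{msr}}\; k_Q^{clin,msr},$$

where $M$ is the reading corrected for every influence quantity that does
not depend on small beam-quality changes ("type I" factors: temperature,
polarity, ion recombination, stem, positioning, ...).  Effects that *do*
change with beam quality ("type II", for a plastic scintillator the
ionization quenching) belong inside $k_Q$.  This package implements that
analysis chain end to end, together with the uncertainty budget and a
synthetic-data generator with known ground truth.

## The correction chain

For a plastic scintillation detector the correction factor is assembled
from a perturbation chain of clin/msr ratios,

$$k_Q = \left[k_{vol}\, P_{scint}\, P_{wall}\, k_{ioq}\right]^{clin}_{msr},$$

with `assemble_kQ()`.  $P_{wall}$ (extracameral components) and
$P_{scint}$ (density and composition of the scintillator relative to
water) come from Monte-Carlo transport and enter as per-field-size
fixture tables (`read_perturbation_fixture()`); the bundled fixture is
synthetic and labelled as such.  $k_{vol}$ and the positioning correction
$k_{pos}$ are computed analytically, and $k_{ioq}$ from Birks' law, as
described below.  `transfer_kQ()` moves a correction factor from a
characterized reference detector to any other detector measured in the
same fields, and `output_factor()` produces $\Omega$.

### Volume averaging and positioning: the convolution model

Near the central axis the relative dose is modelled as a separable
quadratic, $D(x, y) = f(x)\,g(y)$ with $f$ and $g$ second-order
polynomials (`dose_profile_model`, fitted by `fit_quadratic_profile()`).
The measured signal of a detector centred at $(x_0, y_0)$ is the dose
weighted by the normalized height $h$ of the sensitive volume over its
footprint $A$:

$$M(x_0, y_0) = \int_A D(x, y)\, h(x - x_0, y - y_0)\, dA .$$

Because $D$ is quadratic per axis, $M$ reduces *exactly* to a contraction
of the footprint moments $\mu_{ij} = \int x^i y^j h\, dA$ ($i, j \le 2$)
with the Taylor coefficients of $f$ and $g$; the moments themselves are
computed once per geometry by nested adaptive quadrature (relative
tolerance $10^{-8}$, configurable) and cached.  Supported shapes are the
sphere, the cylinder, and the hemisphere-tipped cylinder, with the
symmetry axis parallel or perpendicular to the beam; `detector_preset()`
ships the six studied detector geometries.  For the hemisphere-tipped
cylinder the reference point is the midpoint of the total axial extent,
flat end toward negative $y$ in perpendicular orientation.

Residual positioning error is modelled as a square probability density
of half-widths $(w_x, w_y)$.  The expectation $\langle M\rangle$ and
variance of $M$ under that window are again exact polynomial-moment
contractions (window moments $w^2/3$ and $w^4/5$), so

$$k_{pos} = \frac{M(x_{max}, y_{max})}{\langle M(x_{max}, y_{max})\rangle},
\qquad
k_{vol} = \frac{D(x_{max}, y_{max})}{M(x_{max}, y_{max})}$$

carry no stochastic integration error; the variance is clipped at zero
against roundoff.  Both factors are $\ge 1$ at a concave maximum, and the
test suite checks the whole path against brute-force midpoint grids in
edge-regularized coordinates.

### Ionization quenching

Birks' law gives the light yield of a particle depositing energy between
$E_{min}$ and $E_{max}$ as
$\int A\,/\,(1 + kB\, L_\Delta(E))\, dE$, with $L_\Delta$ the restricted
stopping power (1 keV cutoff) and $kB$ the quenching strength
(`light_yield()`, adaptive quadrature on log energy, relative tolerance
$10^{-7}$).  The quenching correction is the clin/msr ratio of
ideal-to-quenched yields (`kioq_ratio()`); the subscript convention of
$k_Q^{clin,msr}$ fixes the ratio direction as clin over msr.  The
efficiency $A$ cancels.  The default $kB$ is 0.019 cm/MeV with
0.01 cm/MeV as the standard sensitivity alternative
(`kB_sensitivity()`).  Because no restricted stopping-power tabulation
can be redistributed here, the bundled table is a synthetic,
physically-shaped curve for a polystyrene-like scintillator (steep
low-energy rise, broad minimum near 1–2 MeV, density 1.06 g/cm³); the
integrator is table-agnostic and any CSV in the same format can be
substituted.

### Reading corrections

`apply_type1()` enforces the class-specific correction products for
ionization chambers, solid-state detectors and scintillators — supplying
a non-unity factor outside a class's equation (for example `kion` for a
scintillator) is an error, which keeps the type I / type II bookkeeping
honest.  Polarity is corrected from bias-reversal pairs
(`kpol_from_bias_pair()`), recombination at reference conditions by the
pulsed-beam Boag two-voltage method (`boag_two_voltage()`; the pulsed
form is the appropriate one for a flattened 6 MV linac).  Across field
sizes the recombination ratio follows the linearized dose-per-pulse
model $k_{ion} = 1/(1 + B(1 - r))$ with $r$ the polarity-corrected raw
reading ratio (`kion_ratio()`).  The parameter $B$ is calibrated from
scaled-reference measurements: the reference field side is rescaled as
$f'_{msr} = f_{msr}\cdot 100/(SSD + 10)$ so the field size at the
detector plane stays constant while the dose per pulse changes with the
inverse square of the distance (`scale_msr_prime()`,
`make_msr_prime_records()`); `fit_B()` inverts the model per SSD,
averages the extreme SSDs (80 and 110 cm) and reports the max-spread
uncertainty.  `transfer_kion_to_SS()` carries a chamber's recombination
ratio onto a solid-state detector under the assumption that the SSD
scaling leaves the beam quality at the detector plane unchanged.

### Field size and centering

`eleven_point_centering()` implements the step-and-shoot technique: per
axis, two readings on each penumbra near 30 % and 70 % of the central
reading, linear interpolation on each edge to the 50 % level of the
fifth (normalization) reading, center = midpoint of the two crossings,
FWHM = their distance; the eleventh reading at the two-dimensional
center is the output-factor normalization.  The 30 %/70 % levels are
interpreted relative to the central reading and are configurable.  The
equivalent square size is the geometric mean
$S_{clin} = \sqrt{FS_x\, FS_y}$ with first-order propagation
$\sigma_{S} = \tfrac12\sqrt{(FS_y/FS_x)\sigma_x^2 +
(FS_x/FS_y)\sigma_y^2}$ (`equivalent_square()`).

### Curve models

Reading ratios versus $S$ follow the sigmoid-saturation plus
exponential-buildup model
$P_\infty S^n/(l^n + S^n) + S_\infty(1 - e^{-bS})$, normalized to one at
10 cm (`of_model()`).  Correction factors follow the sigmoid-plus-linear
model that is algebraically pinned to one at 10 cm (`kq_model()`).  Both
are fitted by bounded weighted nonlinear least squares
(Levenberg–Marquardt with box constraints, `fit_bounded()`); because the
sigmoid surface has local minima, `fit_of_curve()` and `fit_kq_curve()`
try a data-driven and one or two generic starting points and keep the
lowest deviance.  Default bounds keep the curves physical
($l, n, b, P_\infty, S_\infty > 0$; $q_2 > 0$, $|q_3| < 0.05$ cm⁻¹,
$|q_4| < 10$); the covariance is $s^2 (J^TJ)^{-1}$ with diagonal scaling
because the parameter magnitudes span four orders.  The reference
detector's correction factors are interpolated by a weighted quadratic
in $\log S$ (`fit_reference_kq_polynomial()`): the log abscissa matches
the log-uniform spacing of measured sides and tracks near-unity data to
a few $10^{-4}$, and evaluation outside the fitted range is flagged.

## Uncertainty analysis

`combine_quadrature()` is the $k=1$ root-sum-square.
`fieldsize_contribution()` propagates a field-size uncertainty through a
fitted curve as $|dC/dS|\,\sigma_S / C$.  `build_budget_tables()`
assembles the output-factor budget per field size with the rule
{correction-factor input, statistical raw-reading term of the scenario,
0.1 % stem allowance, 0.1 % residual influence-ratio allowance,
field-size determination term}, for a single-measurement and a
multi-detector scenario; that composition reproduces the printed
combined values of the published budgets it mirrors, and the builder
flags rather than forces any other composition.

`resample_fit_uncertainty()` estimates a fit-uncertainty band by
two-level Monte-Carlo resampling: each of (by default) 1000 iterations
draws one shared Gaussian deviation for the systematic part and
independent per-point deviations for the random part, refits the curve,
and evaluates it on a 0.5 mm grid over 0.5–40 cm; the band is the
pointwise standard deviation.  Non-convergent iterations are dropped and
counted, with failure above 5 %.  One caveat is structural: the
correction-factor model is pinned to one at 10 cm, so a purely
systematic shift is not representable there; when the systematic
component should move the whole curve, pass a free-scale fitter such as
the log-quadratic reference polynomial (the resampler accepts any
`fitter`).

## The synthetic-data generator

The generator defines the study conditions for all recovery tests.

* **Fields** are erf-difference profiles: each edge is
  $\mathrm{erf}((s/2 \mp x)/\sigma)$, with `penumbra_sigma` the erf width
  parameter.  The default $\sigma = 2.75$ mm (80–20 penumbra ≈ 3.3 mm)
  was chosen once so that the nominal 0.6 cm field *measures*
  ≈ 0.66 cm FWHM, as jaw-delimited fields do at depth.  The closed form
  (`field_value()`) provides analytic FWHM and curvature oracles.  A
  consequence of erf edges is that the fitted core curvature of the
  smallest field is $|a_2|/a_0 \approx 0.05$ mm⁻²  — rounder than real
  flat-topped profiles; $k_{pos}$ still rounds to 1.000 there, so
  recovery conclusions are conservative.
* **Sessions** (`make_session()`) inject, per field: the true output
  factor (default `true_output_factor()`, a realistic 6 MV jaw-field
  curve, ≈ 0.70 at a 0.66 cm field), a polarity curve, recombination via
  the linearized model solved self-consistently (so inversion recovers
  the truth exactly at zero noise), an optional detector response
  $1/k_Q(S)$, and i.i.d. multiplicative reading noise (default 0.1 %,
  the scale of readout and machine reproducibility).  Chambers get both
  polarities; the ground truth travels with the table as an attribute.
* **Spectra** (`make_spectra()`) draw one shared two-component set of
  per-particle energy intervals — soft (tens of keV, strongly quenched)
  and hard (hundreds of keV to MeV) — and vary only the soft *energy
  fraction* with field side (default $0.05 + 9\times10^{-4}(s - 10)$,
  monotone non-decreasing).  Larger fields therefore quench more and
  $k_{ioq}$ *increases* with field size, the physically expected
  direction; the deviations stay within a few tenths of a percent.
  Equal soft fractions give literally identical spectra.
* All randomness sits behind one integer seed per artifact (documented
  default 20240101).

`run_recovery_study()` chains everything: profile generation, 11-point
centering with noisy point readings, quadratic fits and $k_{vol}$,
fixture perturbation ratios, quenching ratios, polarity and
recombination corrections (with $B$ refitted from noisy scaled-reference
records), correction-factor assembly, transfer to a second detector, and
output factors, all compared to the generator's truth with a combined
per-field budget.

**What passing tests do and do not show.**  The generator emulates
penumbra shape, reading noise, polarity and dose-per-pulse effects, and
field-size-dependent soft-electron spectra; it does not emulate detector
fluence perturbation (those enter as fixtures), beam-spectrum physics,
scanning-tank positioning drifts, or the flat-topped cores of real
profiles.  Recovery therefore validates the *analysis chain* — that the
estimators invert exactly what the physics model injects — not the
Monte-Carlo inputs themselves.

## Numerical choices and problem sizes

Quadratic fit window: 30 % of the FWHM around the profile center
(configurable) — the region where the quadratic approximation holds;
window centering uses the midpoint of the 50 % crossings because the
arg-max of a flat-topped profile is a tie.  Convexity over a peaked
profile warns and flags rather than fails.  Moments at relative
tolerance $10^{-8}$; quenching integrals at $10^{-7}$ on log energy with
a monotone log-log stopping-power interpolator.  Degenerate inputs fail
loudly: non-bracketing penumbra samples, readings ratios of one in the
$B$ inversion (excluded and logged), rank-deficient fits, empty budgets.

Suite sizes were chosen for a laptop-scale run: 50 random concave models
× 6 geometry/orientation combinations against 400 × 400 brute-force
grids, 20 end-to-end recovery seeds × 12 field sizes, 100-seed
calibration and coverage studies, 1000 resampling iterations.

## Known limitations

Closed-form signal expressions are exact only for the separable
quadratic dose model; outside its valid half-width the quadratic
extrapolates (a warning, not an error, since footprints of the largest
chambers exceed the core of the smallest fields).  The Boag two-voltage
formula is the pulsed-beam form; continuous or flattening-filter-free
beams need a different variant.  The recombination model is linear in
dose per pulse and absorbs initial recombination into the constant; the
stem factor is a scalar allowance, not a spectral model.  The bundled
stopping-power and perturbation tables are synthetic stand-ins shaped
for realism, not reference data.
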