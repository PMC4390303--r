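---
title: "Methods: vial dosimetry and focus-assay calibration"
author: "rifcalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vial dosimetry and focus-assay calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, the choices
behind them, and what the bundled simulations can and cannot show.

## 1. The physical model

### Vial geometry and the S-value

The exposure vessel is modelled as three nested coaxial regions: a blood
cylinder (radius `inner_radius_cm`, height `inner_height_cm`), a
polypropylene wall (`wall_thickness_cm` on all sides), and a shell of dry
air (`air_margin_cm`).  Densities default to 1.0, 0.9 and 1.2·10⁻³ g/cm³.
The defaults (0.48 cm radius, 7.49 cm height, 1 mm wall, 5 cm air) describe
a 5 ml round-bottom tube: note that a radius of 0.48 *mm* — which sometimes
appears in tube schematics — would enclose only ~0.05 ml and could not hold
the 4.5 ml blood/activity mixture, so the centimetre reading is the only
self-consistent one.  The blood cylinder volume at the defaults is ≈5.4 ml;
the nominal `fill_volume_ml = 4.5` is carried separately for dose/activity
bookkeeping and sensitivity checks, while the tally integrates over the
modelled blood region.

The quantity of interest is the S-value: the average absorbed dose rate to
blood per nuclear disintegration occurring in 1 ml of blood
(Gy·s⁻¹·Bq⁻¹·ml).  For a uniform source in a homogeneous self-absorbing
volume this equals the mean energy absorbed in blood per decay (in joules)
divided by the mass of 1 ml of blood (10⁻³ kg); `estimate_svalue()`
implements exactly that tally.  Decays are uniform in the blood cylinder
and emissions isotropic; electron and photon channels are tallied in
separate runs, each scaled by its total yield.

### Decay data

Each bundled nuclide file carries a beta spectrum binned to 5 keV,
discrete conversion and Auger electron lines, and gamma/X-ray lines, in a
plain-text table with per-decay yields.  The spectra were computed offline
with the allowed shape and the relativistic Fermi function (point-Coulomb
with nuclear-radius correction) per branch and rebinned; the resulting
spectrum means match the nominal mean beta energies (181.4 keV for I-131,
134.2 keV for Lu-177) to better than 0.2%.  Rare I-131 branches above the
606.3 keV main endpoint (~0.4% intensity) are folded into the main branch
so the spectrum endpoint equals the nominal maximum energy.  Conversion
and Auger electrons are included deliberately: they add ≈9 keV (I-131) and
≈12 keV (Lu-177) per decay, several percent of the electron channel, which
the S-value resolves.  Sub-keV Auger electrons and sub-10-keV photons are
lumped into single locally-absorbed lines, since their ranges are far
below the vial scale.

### Transport approximations

*Electrons* follow straight-line continuous-slowing-down (CSDA) tracks:
the energy deposited in a region is the energy lost over the in-region
path according to the ESTAR-style water range table (density-scaled in the
wall).  Electrons at or below 10 keV deposit locally.  No multiple
scattering, bremsstrahlung or delta rays: at these energies (≤0.61 MeV,
CSDA range ≤0.23 cm vs a 0.48 cm radius) only a few percent of electron
energy reaches the boundary at all, and angular detours would change the
escape correction by far less than the Monte Carlo uncertainty.

*Photons* use the first-collision kerma approximation: a free path is
sampled from exponential attenuation through the blood/wall/air layers
with material-specific total attenuation coefficients, and at the first
collision the fraction μ_en/μ of the photon energy is deposited locally;
the scattered remainder is counted as escaped.  Photons at or below
10 keV deposit at the emission point.  Build-up from in-vial scatter is
thereby neglected, which biases the photon component somewhat low — an
acceptable trade because photons contribute <4% (I-131) and <1% (Lu-177)
of the total S-value, so the bias on the total is a few per mille.

Physics tables (electron CSDA range in liquid water as soft-tissue
surrogate; photon μ/ρ and μ_en/ρ for water, polypropylene, air) cover
10 keV–1 MeV and are interpolated log-log; energies outside the range are
an error, except residual electron ranges below the 10 keV table floor,
which extrapolate as E ∝ √R toward zero.

Every history conserves energy exactly by construction
(blood + elsewhere + escaped = emitted), a property the test suite
asserts, and each run records its seed and history count; a fixed seed
reproduces the S-value bit for bit.  The Monte Carlo standard error per
component is the sample standard error of the per-history deposit scaled
by the channel yield.

### Dosimetry

`absorbed_dose()` integrates the decaying exposure:
D = c₀·S·(1−e^(−λT))/λ with λ = ln2/T½, reported in mGy, alongside the
initial dose rate c₀·S in mGy/h.  `required_activity()` inverts the rate
formula for experiment planning (activity uniformly mixed into the total
liquid volume).  The bundled `reference_svalues()` are benchmark values
for the default vial from a full coupled-physics transport calculation;
they serve as fixed inputs for dose computation (e.g. 83.34 and
109.6 mGy/MBq after 1 h for Lu-177 and I-131) and as the cross-check
target for `estimate_svalue()`, which reproduces the totals within ~2%.

## 2. The statistical model

Foci totals over `cells_scored` cells are Poisson, so a measurement of
*k* foci in *n* cells has mean *k/n* and standard error √(mean/*n*).  The
net radiation-induced signal subtracts the matched unexposed aliquot's
rate; the two Poisson errors combine in quadrature.  Negative net values
are retained in fitting — clipping would bias low-dose slopes — and only
reported dose point estimates are clipped at zero (and flagged).

Per-dataset and pooled dose-response fits are unweighted OLS.  Weighting
by the Poisson errors is statistically tempting but is not how such
calibration lines are conventionally fitted, and with ~100 cells per
sample the error bars vary only mildly across the dose range; a
`weighted` flag exposes the 1/SE² alternative for sensitivity analysis.

The pooling rule is codified: pool all points into one line when the
one-way ANOVA on per-dataset slopes grouped by subject is non-significant
(p > 0.05); `force_pool` overrides.  Shapiro–Wilk checks (overall and per
subject) accompany the decision.  Slope normality tests on constant
slopes (noise-free simulations) are inapplicable and reported as `NULL`.

The confidence band around the pooled line is the pointwise CI for the
*mean response*, using the OLS parameter covariance and the t quantile
with n−2 degrees of freedom — not a prediction band; the within-sample
counting error is deliberately excluded, matching how such calibration
bands are usually drawn.

Inverse estimation x̂ = (y₀−a)/b propagates the measurement SE and the
parameter covariance by the delta method by default; a Fieller interval
(exact under normality, possibly unbounded when the slope is weak) is
available via `method = "fieller"`.  Both are offered because inverse use
of the calibration is a downstream application rather than part of the
calibration itself.

`reference_calibration()` packages the published-style pooled
coefficients (a = 0.0363 ± 0.0182, b = 0.0147 ± 0.0006, R² = 0.92,
n = 55).  Its parameter covariance must be reconstructed since only the
SEs are given; the OLS identity cov(a,b) = −x̄·se_b² needs the mean
calibration dose, and consistency (Var(a) ≥ x̄²·Var(b)) caps the
compatible x̄ at se_a/se_b ≈ 30 mGy — evidence that the underlying design
oversampled the low-dose end.  The default uses x̄ = 25 mGy; any
inconsistent user-supplied covariance is clamped to zero variance
contribution rather than producing NaN.

## 3. The synthetic-study generator

`default_design()` encodes the study conditions the package is built
around: 3 subjects × 3 blood draws (9 datasets, alternating I-131 and
Lu-177), 55 exposed samples spread evenly over the datasets, doses
uniform on 6–95 mGy, 100 cells per sample, per-dataset background rates
from a Normal(0.17, 0.04) truncated to [0.10, 0.25] foci/cell,
per-dataset slopes Normal(0.0150, 0.0018) RIF/cell·mGy⁻¹, and an induced
intercept of 0.0363 RIF/cell generated separately from the background
(it represents dose-rate-independent induction that survives background
subtraction).  Expected foci per cell at dose x are
b_d + a + m_d·x; totals are Poisson with 100× that mean, and each dataset
shares one unexposed background aliquot, as when one background sample is
scored per blood draw.

What the generator does *not* emulate: foci repair kinetics during and
after incubation, lymphocyte loss at long incubations, scorer-to-scorer
variability, and overdispersion beyond Poisson (the per-cell independence
assumption fixes dispersion at 1; the design carries the hook but no
alternative is implemented).  Passing recovery tests therefore show that
the *fitting pipeline* is unbiased and correctly calibrated for data that
obey the assumed model — not that real scoring data obey it.

A note on the slope spread: the generating SD of 0.0018 is interpreted
directly as the dispersion of true dataset slopes.  Fitted per-dataset
slopes then scatter slightly more (≈0.0025) because ~6-point OLS adds
fitting noise of a similar magnitude; consequently the mean pooled R²
across replicates sits near 0.88 rather than at the noiseless-slope value
of ~0.92.  Both are within the tolerance the recovery checks assert, and
no attempt is made to deconvolve the two sources.

## 4. Numerical choices and problem sizes

* Electron/photon transport cutoffs: 10 keV, local deposit.
* Log-log interpolation for all physics tables; bisection-free analytic
  ray/cylinder intersections with the cap/side tie broken toward the side
  label when equal.
* Truncated-normal background draws by rejection (narrow truncation,
  cheap and exact).
* `decay_integral()` uses `expm1` for small λT.
* Default problem sizes, chosen to make the checks statistically sharp at
  interactive runtimes: 2·10⁵ histories per channel for S-value checks
  (total S to ~0.2% MC error, seconds per nuclide), 200 study replicates
  for recovery (slope mean to ~0.04%), 400 replicates for interval
  coverage (coverage to ~1% MC error).
* All randomness flows through R's global RNG; every stochastic artifact
  (S-values, synthetic studies, reports) records the seed it was built
  from.

## 5. Known limitations

* The vial Monte Carlo is a purpose-built desk model, not a general
  transport code: no coupled electron-photon cascades, no bremsstrahlung,
  no variance reduction, no dose heterogeneity maps — only the average
  dose to blood is in scope.
* First-collision kerma slightly underestimates the photon component
  (no build-up), bounded by the small photon share.
* The straight-line CSDA electron model ignores lateral straggling; its
  escape correction is validated only through the absorbed-fraction
  bounds and the benchmark totals.
* Decay inventories are curated summaries, not a full evaluated file;
  yields below 10⁻⁴ per decay are dropped or lumped.
* The calibration is linear by construction; linear-quadratic responses
  and dicentric-style biodosimetry are out of scope.
* Inverse-dose intervals quantify measurement and calibration-parameter
  uncertainty; they do not cover between-dataset slope heterogeneity, so
  a dose read for a *new* donor carries extra variance the interval does
  not include.
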