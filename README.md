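# rifcalib

Internal blood dosimetry and calibration of the γ-H2AX/53BP1
double-strand-break focus assay, in R.

## The problem

After molecular radiotherapy with I-131 or Lu-177, blood lymphocytes are
continuously irradiated at low, decaying dose rates.  The number of
radiation-induced γ-H2AX/53BP1 foci (RIF) per lymphocyte nucleus is a
biomarker for the DNA double-strand breaks this exposure produces, and a
calibration curve linking RIF/cell to the absorbed dose to blood turns the
assay into a biodosimeter: score foci, read off dose.  Building that curve
in vitro requires two quantitative ingredients this package provides:

1. **Physical dosimetry of the exposure vial.**  Blood is incubated with a
   known activity concentration of the radionuclide in a small tube.  The
   absorbed dose rate to blood per disintegration occurring in 1 ml of
   blood — the S-value, in Gy·s⁻¹·Bq⁻¹·ml — is estimated by Monte Carlo
   transport of the nuclide's full electron (binned beta spectrum plus
   conversion/Auger lines) and photon inventories through the vial
   geometry.  The absorbed dose after an incubation of length *T* at
   initial concentration *c₀* then follows from decay integration:

   D = c₀ · S · (1 − e^(−λT)) / λ,  λ = ln 2 / T½.

2. **Statistical calibration of the foci counts.**  Foci are counted in a
   fixed number of cells; totals are treated as Poisson, background focus
   rates from matched unexposed aliquots are subtracted, each dataset
   (blood draw × nuclide) is fitted by ordinary least squares
   (net RIF/cell = a + b · dose), slope homogeneity across donors is
   checked (Shapiro–Wilk, one-way ANOVA), and a pooled line with a 95%
   confidence band is produced.  Inverse prediction
   x̂ = (y₀ − a)/b with a delta-method or Fieller interval estimates the
   dose of a new sample from its foci count.

A synthetic-study generator reproduces the statistical structure of such
a calibration study (3 donors, 55 samples, 6–95 mGy, 100 cells/sample,
Poisson counts) so that parameter recovery, R², and interval coverage can
be verified by simulation.

## Worked example

```r
library(rifcalib)

## S-value for Lu-177 in the default 5 ml vial
sv <- estimate_svalue(load_nuclide("Lu-177"), histories = 2e5, seed = 42)
sv
#> <svalue Lu-177>  (200000 histories/channel, seed 42)
#>   electrons: 2.265e-11 +- 4.3e-14 Gy/s per Bq/ml  (AF 0.966)
#>   photons:   1.214e-13 +- 8.2e-16               (AF 0.022)
#>   total:     2.277e-11 +- 4.3e-14

## dose after 1 h at 0.5 MBq/ml
absorbed_dose(5e5, 3600, sv, "Lu-177")
#> absorbed dose 40.9 mGy (initial rate 40.99 mGy/h)

## calibrate a (here synthetic) study and estimate a dose from new counts
study  <- generate_study(default_design(), seed = 7)
report <- calibrate_study(study$samples)
report
#> <calibration_report>  55 samples, 9 datasets
#>   mean of slopes 0.0163 +- 0.0022 RIF/cell per mGy
#>   Shapiro-Wilk on slopes: W = 0.854, p = 0.08
#>   one-way ANOVA between subjects: F = 0.63, p = 0.56
#>   pooled fit:
#>     net RIF/cell = 0.0875 (+-0.0422) + 0.0153 (+-0.0007) * dose[mGy]
#>   n = 55, R^2 = 0.892

estimate_dose(report$pooled, summarize_counts(88, 100), summarize_counts(17, 100))
#> estimated dose 40.8 mGy (95% CI 27.1 - 54.5, delta)
```

The electron component dominates the S-value (photons contribute well
under 1% for Lu-177 and under 4% for I-131, since the vial is thin
compared to a photon mean free path), the decay integral shaves a 3600 s
incubation to ≈3592 effective seconds, and the pooled slope of a default
synthetic study recovers the generating 0.0150 RIF/cell·mGy⁻¹ within its
standard error.

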