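# lamotion

Left atrial (LA) function analysis for cine cardiovascular MRI, with 2-point
Dixon cardiac fat quantification and the cohort statistics used to compare
obese type-2-diabetes patients with controls. The package is aimed at
cardiac-imaging researchers who already have tracked endocardial contours
(from a feature-tracking tool) and Dixon fat/water volumes, and want
reproducible phasic strain indices, radial-motion decomposition, fat
readouts and group statistics — plus synthetic phantoms with known ground
truth to validate every step.

## What it computes

**Longitudinal strain.** With `L0` the reference-frame length of the LA
endocardial contour (annulus to annulus) and `Lt` its length at frame *t*:

    Sl(t) = (Lt - L0) / L0

**Radial motion fraction.** The contour is resampled to 120 points and
grouped into 12 segments; with `M0` a segment's reference radius towards the
reference center of mass (held fixed across frames) and `Mt` its radius at
frame *t*:

    Mr(t) = mean over segments of (Mt - M0) / M0

Frame 0 is the cine trigger frame (ventricular end-diastole, minimal LA
volume), so reservoir expansion is positive. Strain rates `SRl` and radial
velocities `Vr` are smoothed finite-difference derivatives (s⁻¹). The three
atrial phases — reservoir (R), conduit (C), atrial contraction / booster (A)
— are delimited by the strain peak and the mid-diastolic shoulder of the
curve, and each curve yields R/C/A amplitudes (with `R = C + A` exact), rate
peaks S′/E′/A′ and the `|E′|/|A′|` and `A/R` ratios. Indices are computed per
long-axis view (2-chamber, 4-chamber, 3-chamber) and averaged globally.

**Mitral-valve decomposition.** Per-segment wall displacement is projected
onto the axis from the LA center of mass to the mitral-valve center (cMr,
intrinsic atrial motion towards the valve) and onto its normal (pMr, which
broadly carries ventricular translational motion); per segment,
`cMr² + pMr² = |displacement|²` exactly.

**Dixon fat.** Intra-myocardial fat fraction as the septal-ROI mean of
`F/(F+W)`; 3D epicardial fat volume by seeded K-means (k = 2) on fat-image
intensities within a whole-heart mask, with the brightest cluster as adipose
tissue, indexed to body surface area (Mosteller).

**Cohort statistics.** Shapiro–Wilk-gated two-group comparison (pooled-
variance t-test or Mann–Whitney U), Pearson correlations, ICC(2,1)
intra-observer agreement, and percent-change summaries.

## Worked example

```r
library(lamotion)

# a beating-LA phantom at control-scale targets, with ventricular translation
ph  <- la_phantom(sl_r = 33.2, sl_a = 16.7, translation_along_mm = 4, seed = 1)
fit <- la_strain(ph$views)
fit
#> <la_strain> 3 view(s): 2-chamber, 4-chamber, 3-chamber
#>   Sl  R/C/A: 33.1 / 16.3 / 16.8 %
#>   Mr  R/C/A: 31.1 / 15.6 / 15.6 %
#>   SRl S'/E'/A': 1.19 / -0.66 / -0.81 1/s (|E'|/|A'| = 0.81)
#>   cMr R/C/A: 17.7 / 8.5 / 9.2 %; pMr R/C/A: 24.0 / 11.8 / 12.1 %
```

The phantom was built with a 33.2% reservoir and 16.7% booster amplitude;
the pipeline recovers 33.1/16.3/16.8 at 20 cine phases. `glance(fit)` returns
the global index row as a tibble, `tidy(fit)` the long curve table, and
`autoplot(fit)` the curves with phase boundaries.

```r
dx <- dixon_phantom(efv_target_ml = 90, myo_ff_pct = 6, noise_sd = 100, seed = 2)
fat_measures(dx$study, bsa_m2 = 1.9, seed = 3)
#> # A tibble: 1 × 4
#>   intramyo_ff_pct efv_ml efv_indexed_ml_m2 ef_fraction_pct
#>             <dbl>  <dbl>             <dbl>           <dbl>
#> 1            7.07     90              47.4            35.5
```

The 90 mL fat shell is recovered exactly at SNR 10 (the ROI fat fraction is
noise-biased at this SNR; see the methods vignette). Cohort-level:

```r
coh <- simulate_cohort(19, 20, seed = 4)   # control vs ObT2D effect sizes
cmp <- compare_cohort(coh, control = "control")
dplyr::filter(cmp, variable %in% c("sl_c", "vr_e_over_a", "efv_abs"))
#>   variable    mean_x  mean_y test_used    p_value pct_change
#> 1 efv_abs     155.   310.    t-test    0.00000328      101.
#> 2 sl_c         15.0   12.2   t-test    0.0795          -18.7
#> 3 vr_e_over_a   1.16   0.747 t-test    0.000482        -35.6
```

`simulate_study()` writes a full on-disk study (contour CSV/JSON, Dixon
NIfTI, subjects table) and `run_pipeline()` takes it end to end to comparison
and correlation tables; `inst/scripts/run_pipeline.R` wraps the latter for
shell use.

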