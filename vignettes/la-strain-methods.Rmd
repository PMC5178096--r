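---
title: "Left atrial strain, radial motion decomposition and cardiac fat: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial strain, radial motion decomposition and cardiac fat: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamotion)
```

## The measurement problem

Early diastolic dysfunction — the precursor of heart failure with preserved
ejection fraction — shows first in left atrial (LA) mechanics, before
chamber volumes or ejection fraction move. Obese patients are exactly the
population in which echocardiographic windows are poor, which motivates
quantifying LA function from cine MRI instead. The inputs to this package
are therefore *tracked endocardial contours*: one ordered 2D point list per
cine phase and long-axis view (2-chamber, 4-chamber, 3-chamber), with frame
times and the two mitral-annulus landmark points per frame. Contour tracking
itself (image registration) is upstream and out of scope; the package trusts
the contours it is given, and its own phantom generator produces them with
known truth.

## Strain and radial motion model

Longitudinal strain is the fractional change of the contour's arc length
relative to the reference frame, `Sl(t) = (Lt − L0)/L0`. The reference is
frame 0, the acquisition's trigger frame at ventricular end-diastole, where
the atrium is near its minimal volume. The choice of reference is a genuine
free parameter of LA strain analysis; this one is the feature-tracking
convention and makes the reservoir peak positive (control-scale reservoir
strain ≈ 33%).

The radial motion fraction resamples each contour to `n_points` (default
120) points at uniform arc length, groups them into `n_segments` (default
12) contiguous segments, and measures each segment's mean distance to the
**reference frame's** center of mass: `Mr(t)` is the segment-average of
`(Mt − M0)/M0`. Two deliberate choices:

* **Expansion is positive.** Both `Sl` and `Mr` are positive when the atrium
  fills. A pure uniform scaling of a contour by `1 + s` about its center of
  mass yields `Sl = Mr = s` to machine precision, which is the package's
  tested exactness contract.
* **The center is frozen at the reference frame.** If the center were
  re-estimated per frame, rigid translation of the atrium (dominated by
  ventricular contraction pulling the annulus) would vanish from `Mr`. It is
  kept on purpose: separating that translation from intrinsic deformation is
  exactly the job of the mitral-valve decomposition below, which needs the
  translation present in the radial signal.

The center of mass is the *arc-length-weighted* polyline centroid (segment
midpoints weighted by segment length), so point density cannot bias it; the
annulus gap is closed with the endpoint chord for this purpose, since the
valve plane bounds the chamber even though it is not atrial wall. The
segment count is configurable because no standard exists; 12 matches common
atrial segmentation granularity and divides the 120-point grid.

## Phases and phasic indices

Atrial function is reported per phase: reservoir (R, filling during
ventricular systole), conduit (C, passive emptying in early diastole) and
atrial contraction / booster (A, active emptying in late diastole). The
reservoir peak is the global maximum of `Sl`. No ECG P-wave timing exists in
the data model, so the contraction onset is found morphologically: the
earliest local minimum of `|dSl/dt|` among interior samples after the peak
and within the last 40% of the cycle — the mid-diastolic shoulder of the
curve. "Earliest" matters: a smooth cyclic curve is also flat at the cycle
end, so the last frames always contain a second derivative minimum that must
not be mistaken for the A-onset. When external timing is available it can be
passed explicitly (`t_a_onset_ms`), which overrides the rule.

Amplitudes are defined so that additivity is exact by construction: `R` is
the curve value at the peak, `A` the drop from contraction onset to cycle
end, and `C = R − A`. Rate indices are the extrema of the derivative curves
per phase window (S′ the reservoir maximum, E′ and A′ the conduit and
contraction minima — negative by convention), and ratio indices are reported
as magnitudes (`|E′|/|A′|`). Cross-view averaging is field-by-field, with
ratios recomputed from averaged numerators and denominators so that the
global row keeps satisfying its own definitions.

Derivatives use centred finite differences with a 3-point moving average
applied to interior samples only (ends stay raw, which keeps a linear ramp's
derivative exact and makes the trapezoid integral of the rate telescope to
`Sl(end) − Sl(0)` exactly on uniform grids). Smoothing is on by default
because 20-phase cine derivatives are noise-amplifying; it can be disabled.
At 20 phases the finite-difference rate peaks are attenuated by roughly
8–10% relative to the continuous-time peaks regardless of smoothing — a
resolution property of the acquisition, not of the implementation — so the
test suite checks rate-peak recovery at 200 phases (where the discretisation
error falls below 2%) and amplitude recovery at the clinical 20 phases.
Strain is stored dimensionless and rendered ×100 in index tables; rate
indices are in s⁻¹ (at a ~1 s cycle the two conventions coincide
numerically, which is how table headers labelled %/s with ~1.4 magnitudes
are interpreted).

## The mitral-valve decomposition

The decomposition separates what the radial signal mixes: per segment and
frame, the displacement vector from the reference position is projected onto
the unit axis from the LA center of mass to the mitral-valve center (the
*centric* component, cMr) and onto its normal (the *perpendicular*
component, pMr, which broadly carries ventricular translation). Three design
choices were open and are fixed as follows:

* **Geometry frozen at the reference frame.** Re-estimating the MV center
  per frame would absorb the translation the decomposition is meant to
  expose.
* **Normalisation.** Projected displacements are divided by the same
  per-segment reference radii `M0` as `Mr`, so cMr/pMr are commensurate with
  the radial motion fraction.
* **Magnitude averaging.** The per-segment projections are signed, and under
  symmetric motion (pure expansion) the signs cancel across segments — a
  signed average would report ≈ 0 where the observed centric reservoir
  amplitude is ≈ 34%. The curves therefore average `|projection|/M0`; the
  signed per-segment projections remain available
  (`decompose_radial(per_segment = TRUE)`), and the identity
  `centric² + perpendicular² = total²` per segment is the tested contract.
  Note `cMr + pMr ≠ Mr` in general: cMr/pMr are orthogonal components of the
  displacement, while Mr is its radial component.

When the LA center coincides with the MV center the axis is undefined and
the operation raises a degenerate-axis error rather than guessing.

## Volumetrics and body metrics

LV volumes use summation of discs over the short-axis stack (shoelace areas
× slice increment), mass as (epicardial − endocardial) end-diastolic volume
× 1.05 g/mL. LA volumes use the biplane area–length formula
`V = 0.85·A_2ch·A_4ch / min(L)` — standard when only long-axis coverage
exists; the single-plane fallback is used when one view is missing. BSA is
Mosteller by default (Du Bois available). None of these formulas is dictated
by the data; they are the field's defaults and are stated here because the
source tables do not specify them.

## Dixon fat quantification

The intra-myocardial fat fraction is the septal-ROI voxel mean of
`F/(F+W)` (2-point Dixon; no T2*/bias correction). Voxels with zero total
signal are excluded and counted in a QC attribute.

Epicardial fat is segmented by K-means with k = 2 on the fat-image
intensities of voxels inside a whole-heart cardiac mask: the decision
surface is a single intensity threshold separating adipose from
non-adipose, and the brightest cluster is adipose. The clustering sees only
intensity values, so the partition is invariant to voxel order and to
positive intensity rescaling, and the seeded initialisation (points sampled
from the data, 10 restarts, 300 iterations, the run deterministic for a
given seed) makes results reproducible. The adipose fraction divides by the
full mask volume, epicardial envelope included. k is configurable, as is a
mode clustering on the voxelwise fat fraction instead of the raw fat image.

## What the phantoms emulate — and what they do not

The LA phantom builds each view as an open elliptical arc (the annulus gap
spans 50° by default; the endpoints are the landmarks), scaled uniformly
about its reference center of mass by `1 + sl(t)` where `sl(t)` is a
piecewise cosine-smoothed profile hitting the target reservoir amplitude at
`t_peak_frac`, the booster amplitude at `t_a_onset_frac`, and zero at the
cycle end. Because the scaling is uniform about the measurement center,
perimeter strain and radial motion fraction both equal `sl(t)` *by
construction* — the truth record never runs the pipeline. Rigid translation
along/across the MV axis (sin² time profile) emulates ventricular motion;
per-view amplitude factors `1 ± view_spread` create genuine inter-view
spread while preserving the cross-view mean. Default conditions mirror the
clinical acquisition: 20 cine phases, 1000 ms cycle, 30 mm base radius,
control-scale amplitudes (reservoir 33.2%, booster 16.7%), phase breakpoints
at 40% and 75% of the cycle.

The Dixon phantom is a concentric-shell volume: blood pool (fat fraction
2%), myocardial shell (configurable fat fraction, default 6%), and an
epicardial fat shell whose volume is hit to within one voxel by selecting
exactly `round(target/voxel volume)` nearest candidate voxels — the truth is
the voxel count, not the nominal target. Class intensities sum to a constant
in-phase signal of 1000, so the noise-free fat fraction is exact; Gaussian
noise is added per image and clipped at zero (magnitude images). SNR 10
(noise SD 100) is the epicardial-segmentation test condition. The ROI fat
fraction is a ratio of clipped Gaussians and acquires a positive bias at
that noise level, so fat-fraction readouts are evaluated at source-image
SNR ≈ 50 (noise SD 20), the realistic regime for a hand-drawn septal ROI on
Dixon source images.

Neither phantom models coil shading, banding, fat–water swaps, partial
volume beyond voxelisation, through-plane motion, or tracking errors in the
contours. Passing phantom recovery therefore validates the *computation* —
formulas, phase logic, clustering, bookkeeping — not the upstream tracking
or MR physics.

The cohort simulator draws per-subject values from normal distributions
with the bundled published group means and SDs (`cohort_reference()`:
control n = 19 vs obese-T2D n = 20 effect sizes). Those numbers are inputs
the simulator targets, not quantities the package claims to reproduce from
images.

## Statistics

Group comparisons follow the clinical analysis plan: Shapiro–Wilk on each
group at α = 0.05; both compatible with normality → two-sided pooled-
variance t-test (the plan says "independent-samples t test" without a Welch
qualifier; Welch is a flag), otherwise Mann–Whitney U (exact enumeration for
tie-free samples of ≤ 8 per group, normal approximation with continuity
correction otherwise). Constant samples route to the rank test. **No
multiple-testing correction is applied** — p-values are reported raw,
matching the source analysis; with ~30 variables per table, a handful of
nominal significances is expected under the null. ICC uses the two-way
single-measure absolute-agreement form ICC(2,1), computed from ANOVA mean
squares (ICC(3,1) by flag); the form was unstated in the source and
ICC(2,1) is the conservative choice for intra-observer designs. Under the
null at the study's group sizes, the gated comparison holds its nominal
size (the suite checks 0.05 ± 0.01 over 10,000 simulations).

## Numerical choices and degenerate inputs

* Resampling interpolates linearly along the polyline and preserves both
  endpoints exactly; idempotent on already-uniform contours to 1e-9 mm.
* Contours need ≥ 8 points per tracked frame (bare geometric primitives
  accept shorter polylines), finite coordinates, no consecutive duplicate
  points; degenerate (zero-length) contours, zero radii, empty ROIs,
  all-zero signal, monotonic strain curves and undefined axes raise classed
  errors (`lamotion_*`) rather than producing numbers.
* K-means degenerates (constant image, or fewer distinct values than k) are
  errors, not silent single-cluster results.
* All randomness flows through explicit seeds; pipeline stages derive their
  seeds from the run seed, the stage name and the subject index, so
  re-running any stage in isolation reproduces it.
* Problem sizes in the test suite: 20 cine phases (clinical) and 200 phases
  (rate-peak convergence); Dixon grids of 32³–64³ voxels at 2.5–5 mm; 20
  noise seeds for fat-volume recovery; 10,000 null simulations for test
  size. These were chosen as the smallest sizes at which the respective
  claims are informative.

## Known limitations

* The A-onset rule is morphological; on curves without a mid-diastolic
  shoulder (e.g. a symmetric triangle) it needs the explicit override, and
  subjects with a very small booster amplitude carry up to one frame of
  sampling error in `Sl_A` at 20 phases.
* The decomposition is 2D per view; no 3D decomposition across views is
  attempted.
* Dixon processing has no fat–water swap correction and does not separate
  paracardial from epicardial compartments; "epicardial fat volume" is the
  adipose cluster within the supplied cardiac mask.
* Echocardiographic quantities appearing alongside the MRI indices in
  cohort tables are inputs, never computed.
* The BMI-adjusted comparison mentioned in the source analysis is not
  implemented, as its model was unspecified; comparisons are unadjusted.
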