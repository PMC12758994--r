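---
title: "Control-point-resolved robustness of cranial VMAT plans under intrafraction motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-point-resolved robustness of cranial VMAT plans under intrafraction motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A VMAT delivery is parameterized by a few hundred control points — discrete
machine states (gantry angle, MLC leaf positions, jaw window, cumulative
monitor units) along the arc. When a patient moves during delivery
(intrafraction motion), the dose of each control point lands in a slightly
different place in the patient. Plan-level robustness metrics (PTV coverage,
GTV near-minimum dose) average this over the whole arc and can hide the fact
that a small subset of control points is responsible for most of the
sensitivity. This package resolves motion sensitivity at the level of the
individual control point, for single-target cranial cases where a rigid 3D
translation is a good model of patient motion (the target is at the
isocenter, the anatomy is nearly water-equivalent, and internal motion is
minimal).

The pipeline is: synthesize a phantom and a VMAT-like plan with
per-control-point dose; simulate a population of time-evolved 3D motion
traces; rigidly translate each control point's dose by the trace
displacement at that control point (no dose recalculation) and accumulate;
and quantify the consequences with DVH metrics at the plan level
(`V_Rx`, GTV `D99%`) and at the control-point level (`mAUC`, `sAUC`),
closing with aperture-area statistics.

## Synthetic plans instead of a clinical export

Clinical plan exports and a commercial dose engine are not available to a
reusable pipeline, so the `synthetic_data` layer generates the study
conditions directly. Its defaults are the reference case used throughout:
a spherical GTV of radius 8.8 mm whose 2 mm isotropic expansion gives a
PTV of about 5.2 cc, prescribed 25 Gy in 5 fractions, delivered in 3 arcs
of 130 control points at 2 degrees spacing (390 control points) on a
1.5 mm isotropic dose grid, normalized so the static plan covers the PTV
at `V_Rx = 99%`. These mirror the plan-characteristic ranges of
single-target cranial cohorts (PTV 0.5–70 cc, 20–56 Gy, 2–4 arcs,
~290–490 control points).

The dose engine is deliberately analytic: the jaw-clipped MLC aperture is
projected divergently from the source through the isocenter plane, blurred
with a Gaussian penumbra (`penumbra_sigma`, default 3 mm — a typical
6 MV penumbra width), and attenuated exponentially with depth from the
surface of a water-equivalent head sphere (`mu_attenuation`, default
0.005 per mm, a megavoltage effective attenuation coefficient in water).
This preserves exactly the features the control-point analysis exploits —
aperture-shaped dose with realistic lateral gradients, scaling linearly
with monitor units — while remaining deterministic and fast. It does not
model heterogeneity corrections, scatter kernels, inverse-square falloff,
or delivery dynamics (leaf speed and dose-rate limits), so absolute dose
levels are only meaningful after the explicit coverage normalization.

Aperture modulation is the design choice that most affects the
control-point statistics. Real VMAT optimizers modulate with sliding
sub-windows, so small apertures present leaf edges *inside* the target
projection where dose gradients are steep. `make_plan()` therefore draws a
mean-one log-normal factor `s` per control point (coefficient of variation
`modulation_cv`, default 0.3, typical of modulated cranial arcs): `s < 1`
keeps a randomly positioned sub-window of fractional width `s` inside the
conformal opening; `s >= 1` over-opens symmetrically. This is what makes
small apertures tend to be motion-sensitive — the mechanism behind the
negative aperture-area-versus-sAUC correlation the analysis looks for.
With `modulation_cv = 0` every aperture is exactly conformal to the PTV
silhouette. Note that per-pair conformality circumscribes the silhouette:
each pair opens to the largest chord across its width, so the staircase
area exceeds the disc area, noticeably for small targets.

Monitor-unit weights are uniform with symmetric Dirichlet jitter
(concentration 50); no published MU distribution exists to emulate, and
mild jitter keeps segment weights realistic without dominating the
aperture effect.

## The motion model

Per-axis displacement distributions for mask-immobilized cranial patients
are taken as printed: means (−0.072, −0.207, 0.195) mm and standard
deviations (1.08, 1.06, 1.58) mm for (x, y, z), an initial-condition limit
of 0.05 mm per axis, and a 3.5 mm cap on the 3D displacement magnitude.
Treatment duration is `(n_cps − 1) × cp_spacing / gantry_speed` with
6 deg/s and 2 deg defaults; inter-arc gaps are ignored (continuous
delivery assumed).

Only the endpoint statistics and the start/cap constraints are published,
not the path law, so the trace construction is the package's own choice,
selected to satisfy every printed constraint simultaneously. Per axis,
with `u = t/T`:

`d(u) = start · (1 − u) + mean · u^g + sd · u^(g − 1/2) · P(u)`

where `start` is uniform in (−0.05, +0.05) mm, and `P(u)` is a
standardized pinned-start Gaussian process (a Brownian bridge plus
`u` times a standard normal endpoint), giving `P(0) = 0`,
`Var P(u) = u`, `P(1) ~ N(0, 1)`. The marginal at time `u` is therefore
`N(mean · u^g, (sd · u^g)^2)` — the endpoint distribution modulated by a
`(t/T)^g` amplitude envelope (`growth_exponent` g, default 1: the
displacement scale ramps linearly in time, matching motion that grows
with treatment duration) — and at `u = 1` it is exactly the endpoint
distribution. Displacements exceeding the 3.5 mm cap are radially
rescaled onto it (with a one-ulp shrink so the bound holds in floating
point); rescaling rather than rejection keeps batch sizes exact and paths
smooth. The Table-2-style parameters are interpreted as describing the
end-of-treatment displacement (not per-interval increments), and axes are
treated as independent — no covariance is published. Rotations are never
modelled.

Interpretation note: with this construction the growth envelope operates
in normalized time, so plans of different lengths sample the same endpoint
distribution on finer or coarser time grids; the absolute duration enters
through the number of control points, not through an extra amplitude
scale. Degenerate parameters (`sd = 0`, `mean = 0`) leave only the
decaying start term, bounded by the 0.05 mm limit.

## Reconstruction and DVH metrics

A patient displacement `+d` shifts the dose seen in the patient frame by
`−d`; `shift_dose()` therefore resamples the grid at positions displaced
by `+d` with trilinear interpolation (mirroring the linear-interpolation
philosophy used for DVH supersampling), filling 0 Gy outside the grid.
Phantom grids carry at least 5 mm of clearance beyond the PTV, so under
the 3.5 mm cap the fill never touches a structure. The scenario dose is
the sum of the shifted control-point doses; the loop streams one trace at
a time so memory stays bounded by the static dose set.

Cumulative DVHs are computed by voxel counting after fivefold
supersampling (trilinear; sphere masks are regenerated analytically on
the fine grid rather than resampled). Control-point DVHs are computed on
the native grid — supersampling is reserved for cumulative dose, where it
is needed to stabilize coverage readouts; this is switchable. The default
bin width is `max(dose)/1000`. Within `cp_auc_metrics()` the static and
shifted curves of one control point share bin edges (width
`max/2000`) so AUC differences carry no binning offset; this matters
because per-control-point AUC differences are of order the bin width.

The central identity — the trapezoidal area under the cumulative DVH
equals the structure mean dose — is what makes `mAUC` a mean-dose
difference. Per control point, across the trace population:
`mAUC = mean(AUC_shifted − AUC_static)` and `sAUC = sd(...)` (sample SD,
n − 1; the divisor is a documented choice). Both are reported in mGy
(`Gy × 1000`) on the total-plan dose scale. The ±0.05 mGy default
threshold on `|mAUC|` separates motion-sensitive from motion-resistant
control points; because its published value corresponds to roughly one
standard deviation of an mAUC population whose absolute scale depends on
prescription and plan size, the threshold is exposed as a parameter with
an `"auto"` mode that sets it to 1 SD of the observed mAUC population.

`D99%` inverts the monotone DVH with ties resolved toward the higher dose;
`V_Rx` interpolates linearly between bins. Coverage normalization bisects
the monotone coverage step function until the bracket collapses, landing
on the smallest factor reaching the target, which also makes
renormalization return exactly 1.

## Statistics

Aperture area against `sAUC` is summarized with a Pearson correlation,
Fisher-z 95% interval and a t-based two-sided p-value, per plan (a pooled
mode across plans exists but is labelled as such). The
sensitive/resistant aperture-area subpopulations are compared with a
two-sided Welch t-test (Satterthwaite degrees of freedom); an
equal-variance pooled mode is retained as a cross-check. No
multiple-testing correction is applied across cases. The coverage summary
reports, per plan and pooled, the range of `delta V_Rx`, the fraction of
traces with any coverage loss, the `D99%` delta range, and V_Rx
normality descriptives.

## Numerical choices and degenerate inputs

* Leaf positions and aperture areas live in the isocenter plane; areas use
  exact rectangle intersection with the jaw window (a fine-pixel
  rasterizer exists only as a test oracle). Collimator rotation is
  ignored — the area is rotation-invariant.
* Coordinates are patient-fixed, right-handed, mm, voxel centres, with the
  isocenter at the GTV centroid on a voxel centre (odd grid dimensions).
* Empty apertures, zero-MU control points, and all-zero dose grids yield
  identically zero dose; empty masks and single-trace sAUC requests raise
  errors; plan validation returns named violations rather than raising.
* One master seed fans out deterministically to per-stage child seeds
  (plan generation, trace batch), so stages can be re-run in isolation and
  whole runs reproduce bit for bit.

## Problem sizes

The shipped workflow and the end-to-end tests use the reference case (390
control points, 33^3-voxel grid, 100 traces, fivefold supersampling),
which runs in a few minutes on one CPU; unit and property tests use
smaller phantoms (about 29^3 voxels, 8–30 control points, tens of traces)
chosen so each check still exercises the full geometry. Trace-constraint
checks run the full 3000-trace population (100 traces for each of 30 plan
lengths drawn from 292–488 control points), which costs only seconds.

## What passing tests do and do not show

The generator emulates the geometry and statistics the analysis relies on
— aperture-shaped per-control-point dose, coverage-normalized static
plans, bounded time-evolved motion. It does not emulate heterogeneous
anatomy, organ-at-risk trade-offs, couch and collimator rotations,
delivery dynamics, or optimizer-specific aperture sequences. Passing the
qualitative acceptance checks (majority coverage loss, variable
control-point sensitivity, nonempty threshold partition, negative
aperture–sAUC correlation under shrinkage-driven modulation) shows the
machinery reproduces the expected motion response on this idealized
geometry; it does not certify the clinical magnitudes of any cohort. On
this small, highly conformal synthetic target the coverage losses are
larger than those reported for clinical cranial cohorts — the synthetic
dose falls off steeply right at the PTV surface, whereas clinical plans
carry shallower gradients and larger targets.

## Known limitations

* Rigid translations only; no rotations or deformation.
* The toy dose engine's absolute dosimetry is meaningful only relative to
  the coverage normalization.
* The mAUC threshold's absolute scale depends on plan dose and length;
  cross-plan comparisons should use the `"auto"` (1 SD) mode.
* DICOM-RT import/export is out of scope; the plan archive is the
  package's own documented container.
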