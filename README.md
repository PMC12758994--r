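# vmatrobust

Control-point-resolved robustness analysis of single-target cranial VMAT
plans under intrafraction motion.

## The problem

A VMAT plan delivers its prescription through hundreds of control points —
discrete machine states (gantry angle, MLC leaf positions, jaw window,
monitor-unit weight) along the arc. Patient motion during delivery
displaces each control point's dose, and plan-level metrics average the
damage over the whole arc. For stereotactic cranial targets, where PTV
margins of 2 mm are under pressure to shrink further, the interesting
question is *which* control points are sensitive to motion. This package
answers it for medical physicists and planning researchers by:

1. generating a synthetic spherical-phantom VMAT plan with
   per-control-point dose (an analytic aperture-projection dose engine on a
   water-equivalent head, normalized so the static plan meets the
   `V_Rx = 99%` coverage goal);
2. simulating populations of control-point-indexed, time-evolved 3D rigid
   motion traces from published per-axis displacement distributions
   (means (−0.072, −0.207, 0.195) mm, SDs (1.08, 1.06, 1.58) mm, initial
   displacement < 0.05 mm, 3D magnitude capped at 3.5 mm, amplitude
   growing with treatment duration at 6°/s gantry speed);
3. reconstructing each motion scenario by rigid translation of every
   control-point dose (no recalculation) and accumulation;
4. scoring plans and control points.

## Core metrics

For structure *S* with cumulative DVH *V_S(D)* (fraction of *S* receiving
at least *D*):

* **V_Rx** — percent of the PTV receiving at least the prescription;
  **D99%** — minimum dose to the best-covered 99% of the GTV, reported as
  the relative difference `100 · (D99_moved − D99_static) / D99_static`.
* **DVH AUC** = ∫ V_S(D) dD, which equals the mean dose in *S*. Per
  control point *c*, across the trace population *t = 1…N*:

  `mAUC(c) = mean_t [AUC_t(c) − AUC_static(c)]`,
  `sAUC(c) = sd_t [AUC_t(c) − AUC_static(c)]` (mGy).

  Control points with `|mAUC| > 0.05 mGy` are classed motion-sensitive;
  aperture-area subpopulations across that threshold are compared with a
  Welch t-test, and aperture area is correlated against sAUC (Pearson,
  Fisher-z 95% CI).

## Worked example

The `analysis/` scripts run the reference case end to end
(`Rscript analysis/01_simulate_plan.R` … `04_cohort_stats.R`), writing
tables under `results/`. Their output on this machine:

```
phantom: GTV 2.86 cc, PTV 5.23 cc on a 33x33x33 grid
plan: 390 control points; aperture area 426 +/- 115 mm^2 (CV 0.27)
normalization factor 2.7731; static PTV V_Rx at the 99% goal
estimated delivery duration: 129.7 s
100 traces x 390 cps; max |d| = 3.500 mm (cap 3.5), max initial axis |d| = 0.0500 mm (limit 0.05)
static V_Rx 99.00%; delta V_Rx -9.16 to -0.15 pp; 100% of traces lose coverage
GTV D99% deltas: -16.69% to -0.09%
mAUC -2.311 to -0.017 mGy (SD 0.591); 377 of 390 control points motion-sensitive at |mAUC| > 0.05 mGy
partition at +/-0.05 mGy: 377 sensitive vs 13 resistant control points
Pearson r = -0.328 (95% CI -0.414 to -0.237), p = 3.03e-11, n = 390
```

Reading it: the static plan exactly meets the 99% coverage goal; every
simulated motion scenario loses some PTV coverage (this small, highly
conformal synthetic target is less forgiving than typical clinical
plans); sensitivity varies strongly across control points (mAUC spans two
orders of magnitude); and smaller MLC apertures associate with higher
motion sensitivity (negative aperture-area vs sAUC correlation), the
behavior that motivates aperture area as a cheap sensitivity surrogate.

The same run is available as one call:

```r
library(vmatrobust)
mf <- run_pipeline(run_config(seed = 1, out_dir = "results/run"))
```

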