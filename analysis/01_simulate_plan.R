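#!/usr/bin/env Rscript
# Stage 1 — synthetic case: spherical cranial phantom and a VMAT-like plan
# at the reference scale (PTV ~5.2 cc, 25 Gy / 5 fx, 3 arcs x 130 control
# points at 2 deg), per-control-point dose, and normalization of the static
# plan to the V_Rx = 99% coverage goal.

suppressPackageStartupMessages(library(vmatrobust))
seed <- 1
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)

phantom <- make_phantom(phantom_spec(gtv_radius = 8.8, ptv_margin = 2))
message(sprintf("phantom: GTV %.2f cc, PTV %.2f cc on a %s grid",
                structure_volume(phantom$structures, "GTV") / 1000,
                structure_volume(phantom$structures, "PTV") / 1000,
                paste(dim(phantom$grid$values), collapse = "x")))

plan <- make_plan(n_arcs = 3, cps_per_arc = 130, rx_dose = 25,
                  n_fractions = 5, phantom = phantom, rng_seed = seed)
stopifnot(length(validate_plan(plan)) == 0)
areas <- vapply(plan$control_points, aperture_area, numeric(1))
message(sprintf("plan: %d control points; aperture area %.0f +/- %.0f mm^2 (CV %.2f)",
                length(plan$control_points), mean(areas), sd(areas),
                sd(areas) / mean(areas)))

cp_doses <- compute_plan_dose(plan, phantom)
k <- normalize_plan_dose(cp_doses, phantom$structures, plan$rx_dose)
cp_doses <- scale_dose(cp_doses, k)
static <- sum_dose(cp_doses)
message(sprintf("normalization factor %.4f; static PTV V_Rx at the 99%% goal",
                k))

write_plan_archive("results/plan_archive", plan, phantom)
saveRDS(list(phantom = phantom, plan = plan, cp_doses = cp_doses,
             static = static, seed = seed),
        "results/cache/state_plan.rds")
message("stage 1 done -> results/plan_archive, results/cache/state_plan.rds")
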