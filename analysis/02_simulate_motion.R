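#!/usr/bin/env Rscript
# Stage 2 — intrafraction motion: 100 control-point-indexed 3D rigid motion
# traces from the published per-axis displacement distributions, with the
# 0.05 mm initial-condition limit, duration-keyed amplitude growth
# (6 deg/s gantry, 2 deg spacing) and the 3.5 mm magnitude cap.

suppressPackageStartupMessages(library(vmatrobust))
state <- readRDS("results/cache/state_plan.rds")
n_cps <- length(state$cp_doses)

params <- motion_model_params()
message(sprintf("estimated delivery duration: %.1f s",
                treatment_duration(n_cps, params)))

traces <- generate_batch(100, n_cps, params, master_seed = state$seed + 1)
df <- traces_to_df(traces)
write.csv(df, "results/traces.csv", row.names = FALSE)

mag <- sqrt(df$dx^2 + df$dy^2 + df$dz^2)
message(sprintf("100 traces x %d cps; max |d| = %.3f mm (cap 3.5), max initial axis |d| = %.4f mm (limit 0.05)",
                n_cps, max(mag), max(abs(df[df$cp_index == 0, c("dx", "dy", "dz")]))))

saveRDS(traces, "results/cache/traces.rds")
message("stage 2 done -> results/traces.csv")
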