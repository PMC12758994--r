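#' Configuration of an end-to-end robustness run
#'
#' Bundles every tunable of the pipeline with defaults mirroring the
#' reference synthetic case (PTV about 5.2 cc, 25 Gy in 5 fractions, 3 arcs
#' of 130 control points at 2 degrees, 1.5 mm grid, 100 motion traces).
#'
#' @param gtv_radius GTV radius (mm); 8.8 mm gives a ~5.2 cc PTV with the
#'   2 mm margin.
#' @param ptv_margin GTV-to-PTV margin (mm).
#' @param grid_spacing Dose-grid spacing (mm).
#' @param rx_dose Prescription (Gy).
#' @param n_fractions Fractions.
#' @param n_arcs Arcs.
#' @param cps_per_arc Control points per arc.
#' @param cp_spacing Gantry spacing (deg).
#' @param modulation_cv Aperture modulation coefficient of variation.
#' @param n_traces Motion traces per scenario batch.
#' @param threshold_mgy mAUC sensitivity threshold (mGy) or `"auto"`.
#' @param target_vrx Static coverage normalization target (percent).
#' @param supersample_factor DVH supersampling factor.
#' @param motion A [motion_model_params()].
#' @param dose_params A [toy_dose_params()].
#' @param seed Master seed; fans out to named per-stage child seeds.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(gtv_radius = 8.8, ptv_margin = 2, grid_spacing = 1.5,
                       rx_dose = 25, n_fractions = 5, n_arcs = 3,
                       cps_per_arc = 130, cp_spacing = 2,
                       modulation_cv = 0.3, n_traces = 100,
                       threshold_mgy = 0.05, target_vrx = 99,
                       supersample_factor = 5,
                       motion = motion_model_params(),
                       dose_params = toy_dose_params(), seed = 1,
                       out_dir = tempfile("vmatrobust-run-")) {
  structure(
    list(gtv_radius = gtv_radius, ptv_margin = ptv_margin,
         grid_spacing = grid_spacing, rx_dose = rx_dose,
         n_fractions = n_fractions, n_arcs = n_arcs,
         cps_per_arc = cps_per_arc, cp_spacing = cp_spacing,
         modulation_cv = modulation_cv, n_traces = n_traces,
         threshold_mgy = threshold_mgy, target_vrx = target_vrx,
         supersample_factor = supersample_factor, motion = motion,
         dose_params = dose_params, seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

# Deterministic named child seeds fanned out from the master seed.
.stage_seeds <- function(master) {
  set.seed(master)
  s <- sample.int(2147483646L, 3)
  list(plan = s[1], traces = s[2], spare = s[3])
}

#' Run the full control-point robustness pipeline
#'
#' Orchestrates every stage: phantom and plan generation, per-control-point
#' static dose and coverage normalization, motion-trace batch, streamed
#' scenario reconstruction with plan-level metrics, per-control-point
#' mAUC/sAUC metrics, and the aperture-area statistics. All tables are
#' written as CSV under `config$out_dir` together with a JSON manifest
#' recording seeds, the configuration, and file checksums; rerunning with
#' the same configuration reproduces every numeric output exactly.
#'
#' Scenario cumulative doses are streamed one trace at a time, so resident
#' memory stays bounded by the static per-control-point dose set.
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress, default `TRUE`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }
  if (config$n_traces < 2) {
    stop("pipeline stage 'cp_metrics' requires n_traces >= 2: ",
         "sAUC is a standard deviation across traces", call. = FALSE)
  }

  phantom <- stage("phantom", {
    make_phantom(phantom_spec(config$gtv_radius, config$ptv_margin,
                              config$grid_spacing))
  })
  plan <- stage("plan", {
    make_plan(config$n_arcs, config$cps_per_arc, config$rx_dose,
              config$n_fractions, phantom, rng_seed = seeds$plan,
              cp_spacing = config$cp_spacing,
              modulation_cv = config$modulation_cv)
  })
  cp_doses <- stage("dose", {
    compute_plan_dose(plan, phantom, config$dose_params)
  })
  k <- stage("normalize", {
    normalize_plan_dose(cp_doses, phantom$structures, config$rx_dose,
                        target_vrx = config$target_vrx,
                        supersample_factor = config$supersample_factor)
  })
  cp_doses <- scale_dose(cp_doses, k)
  static <- sum_dose(cp_doses)

  traces <- stage("traces", {
    generate_batch(config$n_traces, length(cp_doses), config$motion,
                   master_seed = seeds$traces)
  })
  write.csv(traces_to_df(traces), file.path(out, "traces.csv"),
            row.names = FALSE)

  sm <- stage("scenarios", {
    cums <- lapply(traces, function(tr) {
      reconstruct_scenario(cp_doses, tr)$cumulative
    })
    names(cums) <- vapply(traces, `[[`, "", "trace_id")
    m <- scenario_metrics(static, cums, phantom$structures, config$rx_dose,
                          config$supersample_factor)
    m$trace_id <- names(cums)
    m
  })
  write.csv(sm, file.path(out, "scenario_metrics.csv"), row.names = FALSE)

  cpm <- stage("cp_metrics", {
    cp_auc_metrics(cp_doses, traces, phantom$structures,
                   threshold_mgy = config$threshold_mgy, plan = plan)
  })
  write.csv(cpm, file.path(out, "cp_metrics.csv"), row.names = FALSE)

  stats_out <- stage("stats", {
    part <- partition_control_points(cpm, config$threshold_mgy)
    res <- list(threshold_mgy = part$threshold_mgy,
                n_sensitive = nrow(part$sensitive),
                n_resistant = nrow(part$resistant))
    res$correlation <- unclass(correlate_aperture_sensitivity(cpm))
    if (nrow(part$sensitive) >= 2 && nrow(part$resistant) >= 2) {
      res$welch <- unclass(welch_subpopulation_test(
        part$sensitive$aperture_area_mm2, part$resistant$aperture_area_mm2))
    }
    res$coverage <- coverage_summary(sm)
    res
  })
  write.csv(stats_out$coverage, file.path(out, "coverage_summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(stats_out[setdiff(names(stats_out), "coverage")],
                       file.path(out, "stats_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_plan_archive(file.path(out, "plan_archive"), plan, phantom)

  files <- c("traces.csv", "scenario_metrics.csv", "cp_metrics.csv",
             "coverage_summary.csv", "stats_summary.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("vmatrobust")),
    r_version = R.version.string,
    master_seed = config$seed, stage_seeds = seeds,
    normalization_factor = k,
    vrx_static = attr(sm, "vrx_static"),
    d99_static = attr(sm, "d99_static"),
    config = .config_as_list(config),
    checksums = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out, files)))), files),
    complete = TRUE
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

.config_as_list <- function(config) {
  cl <- unclass(config)
  cl$motion <- unclass(cl$motion)
  cl$dose_params <- unclass(cl$dose_params)
  cl
}
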