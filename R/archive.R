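#' Write a plan archive
#'
#' Persists a plan (structured JSON text), the phantom specification, and
#' optionally the per-control-point dose grids and structure masks (RDS
#' arrays carrying origin/spacing) into a directory.
#'
#' @param path Directory to create/fill.
#' @param plan A [plan_spec()].
#' @param phantom Optional phantom from [make_phantom()].
#' @param cp_doses Optional list of per-control-point [dose_grid()].
#' @return `path`, invisibly.
#' @export
write_plan_archive <- function(path, plan, phantom = NULL, cp_doses = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pl <- list(
    plan_id = plan$plan_id, rx_dose = plan$rx_dose,
    n_fractions = plan$n_fractions, n_arcs = plan$n_arcs,
    cp_spacing = plan$cp_spacing,
    control_points = lapply(plan$control_points, function(cp) {
      list(index = cp$index, gantry_angle = cp$gantry_angle,
           mu_weight = cp$mu_weight, bank_a = cp$bank_a, bank_b = cp$bank_b,
           jaws = as.list(cp$jaws))
    })
  )
  jsonlite::write_json(pl, file.path(path, "plan.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(phantom)) {
    jsonlite::write_json(unclass(phantom$spec),
                         file.path(path, "phantom.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(cp_doses)) {
    saveRDS(cp_doses, file.path(path, "cp_doses.rds"))
  }
  invisible(path)
}

#' Read a plan archive
#'
#' @param path Directory written by [write_plan_archive()].
#' @return List with `plan` ([plan_spec()]), `phantom` (rebuilt via
#'   [make_phantom()] when present) and `cp_doses` (when present).
#' @export
read_plan_archive <- function(path) {
  pl <- jsonlite::read_json(file.path(path, "plan.json"),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cps <- lapply(pl$control_points, function(cp) {
    control_point(index = cp$index, gantry_angle = cp$gantry_angle,
                  mu_weight = cp$mu_weight,
                  bank_a = unlist(cp$bank_a), bank_b = unlist(cp$bank_b),
                  jaws = unlist(cp$jaws))
  })
  plan <- plan_spec(pl$plan_id, pl$rx_dose, pl$n_fractions, pl$n_arcs, cps,
                    pl$cp_spacing)
  out <- list(plan = plan, phantom = NULL, cp_doses = NULL)
  pj <- file.path(path, "phantom.json")
  if (file.exists(pj)) {
    ps <- jsonlite::read_json(pj, simplifyVector = TRUE)
    out$phantom <- make_phantom(phantom_spec(
      gtv_radius = ps$gtv_radius, ptv_margin = ps$ptv_margin,
      grid_spacing = ps$grid_spacing, grid_extent = ps$grid_extent,
      head_radius = ps$head_radius))
  }
  dr <- file.path(path, "cp_doses.rds")
  if (file.exists(dr)) out$cp_doses <- readRDS(dr)
  out
}
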