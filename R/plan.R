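#' Control point of a VMAT plan
#'
#' A control point is one discrete machine state along the arc: gantry angle,
#' the fraction of the plan's monitor units delivered in this segment, the
#' leaf-tip positions of the two opposed MLC banks along the leaf-travel
#' axis, and the jaw window. Positions are mm in the isocenter plane; for
#' each pair `bank_a <= bank_b` means the pair is open by `bank_b - bank_a`.
#'
#' @param index 0-based position in delivery order.
#' @param gantry_angle Gantry angle in degrees.
#' @param mu_weight Fraction of plan monitor units in `[0, 1]`.
#' @param bank_a,bank_b Numeric vectors of per-pair leaf-tip positions (mm).
#' @param jaws Named numeric vector `c(x1, x2, y1, y2)` (mm), `x1 < x2`,
#'   `y1 < y2`.
#' @return An object of class `control_point`.
#' @export
control_point <- function(index, gantry_angle, mu_weight, bank_a, bank_b,
                          jaws = c(x1 = -110, x2 = 110, y1 = -110, y2 = 110)) {
  stopifnot(length(bank_a) == length(bank_b),
            is.numeric(gantry_angle), length(gantry_angle) == 1,
            is.numeric(mu_weight), length(mu_weight) == 1)
  jaws <- jaws[c("x1", "x2", "y1", "y2")]
  structure(
    list(index = as.integer(index), gantry_angle = gantry_angle,
         mu_weight = mu_weight, bank_a = as.numeric(bank_a),
         bank_b = as.numeric(bank_b), jaws = jaws),
    class = "control_point"
  )
}

#' VMAT plan specification
#'
#' Bundles the prescription and the ordered control-point sequence of a
#' single-isocenter VMAT plan. Control points are evenly spaced in gantry
#' angle (`cp_spacing`, default 2 degrees) and their `mu_weight`s sum to one.
#'
#' @param plan_id Identifier string.
#' @param rx_dose Total prescription dose (Gy).
#' @param n_fractions Number of fractions.
#' @param n_arcs Number of VMAT arcs.
#' @param control_points List of [control_point()] in delivery order.
#' @param cp_spacing Gantry-angle spacing between consecutive control points
#'   within an arc (degrees).
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(plan_id, rx_dose, n_fractions, n_arcs, control_points,
                      cp_spacing = 2) {
  stopifnot(is.list(control_points), length(control_points) >= 1,
            rx_dose > 0, n_fractions >= 1, n_arcs >= 1, cp_spacing > 0)
  structure(
    list(plan_id = plan_id, rx_dose = rx_dose,
         n_fractions = as.integer(n_fractions), n_arcs = as.integer(n_arcs),
         control_points = control_points, cp_spacing = cp_spacing),
    class = "plan_spec"
  )
}

#' @export
print.plan_spec <- function(x, ...) {
  cat(sprintf("VMAT plan '%s': %.4g Gy in %d fx, %d arc(s), %d control points (%g deg spacing)\n",
              x$plan_id, x$rx_dose, x$n_fractions, x$n_arcs,
              length(x$control_points), x$cp_spacing))
  invisible(x)
}

#' Validate a plan specification
#'
#' Checks the structural invariants of a [plan_spec()] and its control
#' points. Violations are returned, not raised, so a plan can be audited in
#' one pass; an empty result means the plan is well formed.
#'
#' Checked rules: monitor-unit weights non-negative and summing to 1 (within
#' 1e-9); per pair `bank_a <= bank_b`; jaw windows ordered (`x1 < x2`,
#' `y1 < y2`); consistent leaf-pair counts across control points; control
#' point count divisible by the arc count.
#'
#' @param plan A [plan_spec()].
#' @return Character vector of human-readable violations, empty if none.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "plan_spec"))
  v <- character(0)
  cps <- plan$control_points
  w <- vapply(cps, function(cp) cp$mu_weight, numeric(1))
  if (any(w < 0)) {
    v <- c(v, sprintf("cp %d: negative mu_weight", which(w < 0)[1] - 1L))
  }
  if (abs(sum(w) - 1) > 1e-9) {
    v <- c(v, sprintf("plan: mu_weights sum to %.10f, not 1", sum(w)))
  }
  npairs <- vapply(cps, function(cp) length(cp$bank_a), integer(1))
  if (length(unique(npairs)) > 1) {
    v <- c(v, "plan: inconsistent leaf-pair counts across control points")
  }
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    if (any(cp$bank_a > cp$bank_b + 1e-12)) {
      v <- c(v, sprintf("cp %d: bank_a > bank_b (leaf overlap) in pair %d",
                        i - 1L, which(cp$bank_a > cp$bank_b + 1e-12)[1]))
    }
    j <- cp$jaws
    if (!(j[["x1"]] < j[["x2"]] && j[["y1"]] < j[["y2"]])) {
      v <- c(v, sprintf("cp %d: jaw window not ordered", i - 1L))
    }
    if (!is.finite(cp$gantry_angle)) {
      v <- c(v, sprintf("cp %d: non-finite gantry angle", i - 1L))
    }
  }
  if (length(cps) %% plan$n_arcs != 0) {
    v <- c(v, sprintf("plan: %d control points not divisible into %d arcs",
                      length(cps), plan$n_arcs))
  }
  v
}
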