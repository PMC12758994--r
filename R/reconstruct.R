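#' Rigidly shift a dose grid
#'
#' Resamples the dose at positions displaced by `-d`: when the patient moves
#' by `+d`, the dose distribution seen in the patient frame shifts by `-d`,
#' i.e. the output voxel at position `x` takes the input value at `x + d`.
#' Resampling is trilinear; positions sampling outside the original grid
#' take 0 Gy (grids are generated padded so this never touches the
#' structures under the 3.5 mm motion cap).
#'
#' @param dose A [dose_grid()].
#' @param d Length-3 displacement of the patient (mm).
#' @return A [dose_grid()] on the same geometry.
#' @export
shift_dose <- function(dose, d) {
  stopifnot(inherits(dose, "dose_grid"))
  if (length(d) != 3 || any(!is.finite(d))) {
    stop("displacement must be a finite length-3 vector", call. = FALSE)
  }
  s <- d / dose$spacing                  # sample input at index + s
  f <- floor(s)
  w <- s - f
  dims <- dim(dose$values)
  out <- array(0, dims)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    wt <- (if (c1) w[1] else 1 - w[1]) *
          (if (c2) w[2] else 1 - w[2]) *
          (if (c3) w[3] else 1 - w[3])
    if (wt == 0) next
    o <- f + c(c1, c2, c3)
    i1 <- max(1, 1 - o[1]):min(dims[1], dims[1] - o[1])
    i2 <- max(1, 1 - o[2]):min(dims[2], dims[2] - o[2])
    i3 <- max(1, 1 - o[3]):min(dims[3], dims[3] - o[3])
    if (i1[1] > i1[length(i1)] || i2[1] > i2[length(i2)] ||
        i3[1] > i3[length(i3)]) next
    out[i1, i2, i3] <- out[i1, i2, i3] +
      wt * dose$values[i1 + o[1], i2 + o[2], i3 + o[3]]
  }
  dose_grid(out, dose$origin, dose$spacing)
}

# Trilinearly sampled values of `values` at mask voxels displaced by +d (in
# mm), for a precomputed .mask_index(). Requires the shifted bounding box to
# stay inside the grid — guaranteed by the phantom padding under the motion
# cap, and checked.
.shift_sample <- function(values, midx, spacing, d) {
  s <- d / spacing
  f <- floor(s)
  w <- s - f
  dims <- midx$dim
  if (any(midx$lo + f < 1) || any(midx$hi + f + 1 > dims)) {
    stop("shift moves the mask outside the dose grid; pad the grid",
         call. = FALSE)
  }
  stride <- c(1, dims[1], dims[1] * dims[2])
  base <- midx$lin + sum(f * stride)
  out <- numeric(length(base))
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    wt <- (if (c1) w[1] else 1 - w[1]) *
          (if (c2) w[2] else 1 - w[2]) *
          (if (c3) w[3] else 1 - w[3])
    if (wt == 0) next
    out <- out + wt * values[base + c1 + c2 * stride[2] + c3 * stride[3]]
  }
  out
}

#' Reconstruct the dose of one motion scenario
#'
#' Applies the control-point-specific rigid shifts of a motion trace to the
#' per-control-point dose grids and accumulates them: dose volumes are
#' rigidly translated without recalculation, then summed. Linear in each
#' control-point dose and invariant to control-point order.
#'
#' @param cp_doses List of per-control-point [dose_grid()].
#' @param trace A [generate_trace()] result with one displacement per
#'   control point.
#' @param keep_per_cp Keep the individual shifted grids (memory-heavy),
#'   default `FALSE`.
#' @return An object of class `scenario_dose`: list with `trace_id`,
#'   `cumulative` ([dose_grid()]) and optionally `per_cp_shifted`.
#' @export
reconstruct_scenario <- function(cp_doses, trace, keep_per_cp = FALSE) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- length(cp_doses)
  if (nrow(trace$displacements) != n) {
    stop("trace has ", nrow(trace$displacements),
         " control points but the plan has ", n, call. = FALSE)
  }
  g1 <- cp_doses[[1]]
  acc <- array(0, dim(g1$values))
  per <- if (keep_per_cp) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sh <- shift_dose(cp_doses[[i]], trace$displacements[i, ])
    acc <- acc + sh$values
    if (keep_per_cp) per[[i]] <- sh
  }
  structure(
    list(trace_id = trace$trace_id,
         cumulative = dose_grid(acc, g1$origin, g1$spacing),
         per_cp_shifted = per),
    class = "scenario_dose"
  )
}
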