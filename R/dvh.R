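#' Supersample a dose grid by linear interpolation
#'
#' Resamples the dose onto a grid with `factor`-fold finer spacing covering
#' the same physical extent, by separable (trilinear) linear interpolation.
#' Linear fields are reproduced exactly; `factor = 1` is the identity.
#' Fivefold supersampling is applied to cumulative dose grids before DVH
#' analysis.
#'
#' @param dose A [dose_grid()].
#' @param factor Integer supersampling factor (>= 1), default 5.
#' @return A [dose_grid()] with `(n - 1) * factor + 1` voxels per axis.
#' @export
supersample <- function(dose, factor = 5) {
  stopifnot(inherits(dose, "dose_grid"), factor >= 1, factor == round(factor))
  if (factor == 1) return(dose)
  vals <- dose$values
  for (ax in 1:3) {
    n <- dim(vals)[ax]
    m <- (n - 1L) * factor + 1L
    pos <- (seq_len(m) - 1) / factor     # in old index units, 0-based
    i0 <- pmin(floor(pos), n - 2)
    w <- pos - i0
    lo <- i0 + 1L
    d <- dim(vals)
    if (ax == 1) {
      vals <- vals[lo, , , drop = FALSE] * (1 - w) +
        vals[lo + 1L, , , drop = FALSE] * w
    } else if (ax == 2) {
      wa <- rep(w, each = d[1])
      vals <- vals[, lo, , drop = FALSE] * (1 - wa) +
        vals[, lo + 1L, , drop = FALSE] * wa
    } else {
      wa <- rep(w, each = d[1] * d[2])
      vals <- vals[, , lo, drop = FALSE] * (1 - wa) +
        vals[, , lo + 1L, drop = FALSE] * wa
    }
  }
  dose_grid(vals, dose$origin, dose$spacing / factor)
}

#' Supersample a structure set
#'
#' Regenerates structure masks on the supersampled geometry of a reference
#' grid. Structures with stored analytic sphere parameters are regenerated
#' exactly (voxel-centre test on the fine grid); any others are resampled by
#' nearest-neighbour membership.
#'
#' @param structures A [structure_set()].
#' @param grid The coarse reference [dose_grid()].
#' @param factor Supersampling factor.
#' @return A [structure_set()] congruent with `supersample(grid, factor)`.
#' @export
supersample_structures <- function(structures, grid, factor = 5) {
  if (factor == 1) return(structures)
  fine <- supersample(dose_grid(grid$values * 0, grid$origin, grid$spacing),
                      factor)
  xs <- grid_axis(fine, 1); ys <- grid_axis(fine, 2); zs <- grid_axis(fine, 3)
  masks <- list()
  for (nm in names(structures$masks)) {
    sp <- structures$spheres[[nm]]
    if (!is.null(sp)) {
      masks[[nm]] <- .sphere_mask(xs, ys, zs, sp$center, sp$radius)
    } else {
      near <- function(n) rep(seq_len(n), each = factor)[seq_len((n - 1) * factor + 1) + (factor %/% 2)]
      d <- structures$dim
      i1 <- pmin(round((xs - structures$origin[1]) / structures$spacing[1]) + 1, d[1])
      i2 <- pmin(round((ys - structures$origin[2]) / structures$spacing[2]) + 1, d[2])
      i3 <- pmin(round((zs - structures$origin[3]) / structures$spacing[3]) + 1, d[3])
      masks[[nm]] <- structures$masks[[nm]][i1, i2, i3]
    }
  }
  structure_set(masks, fine, spheres = structures$spheres)
}

# Cumulative DVH from a vector of structure dose values.
.dvh_from_values <- function(vals, bin_width = NULL, max_dose = NULL,
                             structure_name = NA_character_,
                             scenario_id = NA_character_) {
  n <- length(vals)
  stopifnot(n > 0)
  if (is.null(max_dose)) max_dose <- max(vals)
  if (max_dose <= 0) max_dose <- .Machine$double.eps
  if (is.null(bin_width)) bin_width <- max_dose / 1000
  edges <- seq(0, by = bin_width,
               length.out = max(2L, ceiling(max_dose / bin_width) + 1L))
  b <- findInterval(vals, edges)
  counts <- tabulate(b, nbins = length(edges))
  n_ge <- rev(cumsum(rev(counts)))
  structure(
    list(dose = edges, volume_fraction = 100 * n_ge / n,
         structure = structure_name, scenario_id = scenario_id),
    class = "dvh_curve"
  )
}

#' Cumulative dose-volume histogram of a structure
#'
#' Voxel-counting cumulative DVH: at each dose bin edge, the percentage of
#' structure voxels receiving at least that dose. The curve starts at 100%
#' and is non-increasing. The default bin width is `max(dose)/1000`.
#'
#' @param dose A [dose_grid()] (already supersampled if desired).
#' @param mask Logical array congruent with the dose grid, non-empty.
#' @param bin_width Dose bin width (Gy); default `max/1000`.
#' @param max_dose Upper end of the dose axis (Gy); defaults to the maximum
#'   structure dose. Supplying a common value makes curves from different
#'   scenarios share bin edges.
#' @param structure_name,scenario_id Labels stored on the curve.
#' @return An object of class `dvh_curve` with fields `dose` (bin edges,
#'   Gy), `volume_fraction` (percent), `structure`, `scenario_id`.
#' @export
compute_dvh <- function(dose, mask, bin_width = NULL, max_dose = NULL,
                        structure_name = NA_character_,
                        scenario_id = NA_character_) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!any(mask)) stop("empty structure mask", call. = FALSE)
  .dvh_from_values(dose$values[mask], bin_width, max_dose,
                   structure_name, scenario_id)
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative DVH at `dose`; 100% below the
#' first edge, 0% beyond the last.
#'
#' @param dvh A [compute_dvh()] curve.
#' @param dose Query dose (Gy), e.g. the prescription for V_Rx.
#' @return Volume percentage.
#' @export
v_at_dose <- function(dvh, dose) {
  x <- dvh$dose; y <- dvh$volume_fraction
  if (dose <= x[1]) return(100)
  if (dose >= x[length(x)]) {
    return(if (dose == x[length(x)]) y[length(y)] else 0)
  }
  stats::approx(x, y, xout = dose)$y
}

#' Minimum dose to the best-covered fraction of a structure
#'
#' Inverse interpolation of the cumulative DVH: the highest dose `D` such
#' that at least `volume` percent of the structure receives `>= D`. Ties
#' (flat curve segments at exactly `volume`) resolve toward the higher dose.
#'
#' @param dvh A [compute_dvh()] curve.
#' @param volume Volume percentage, e.g. 99 for D99%.
#' @return Dose in Gy.
#' @export
d_at_volume <- function(dvh, volume = 99) {
  x <- dvh$dose; y <- dvh$volume_fraction
  if (volume > y[1]) return(0)
  idx <- max(which(y >= volume))
  if (idx == length(y) || y[idx] == volume) return(x[idx])
  x[idx] + (y[idx] - volume) / (y[idx] - y[idx + 1]) * (x[idx + 1] - x[idx])
}

#' Area under the cumulative DVH
#'
#' Trapezoidal integral of the volume fraction (as a unitless fraction) over
#' dose. For a cumulative DVH this equals the structure's mean dose, which
#' is what makes per-control-point AUC differences mean-dose differences.
#'
#' @param dvh A [compute_dvh()] curve.
#' @return Mean dose (Gy).
#' @export
dvh_auc <- function(dvh) {
  x <- dvh$dose; y <- dvh$volume_fraction / 100
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
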