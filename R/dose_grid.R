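#' Regular 3D dose grid
#'
#' A scalar dose array on a regular, axis-aligned 3D grid in patient-fixed
#' coordinates (mm). `origin` is the physical coordinate of the centre of
#' voxel `[1, 1, 1]`; voxel `[i, j, k]` is at
#' `origin + (c(i, j, k) - 1) * spacing`. By construction of the synthetic
#' phantoms the isocenter (0, 0, 0) coincides with the GTV centroid and with
#' a voxel centre.
#'
#' @param values 3D numeric array of dose (Gy), non-negative.
#' @param origin Length-3 numeric, mm.
#' @param spacing Length-3 numeric (or scalar, recycled), mm, positive.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  stopifnot(all(spacing > 0))
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dose_grid %dx%dx%d, spacing (%.3g, %.3g, %.3g) mm, max %.4g Gy\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              max(x$values)))
  invisible(x)
}

#' Physical voxel-centre coordinates of a grid axis
#' @param grid A [dose_grid()].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of coordinates (mm).
#' @export
grid_axis <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Structure set on a dose grid
#'
#' Named boolean masks (GTV, PTV, optional organs at risk) congruent with a
#' [dose_grid()]. For analytically defined spherical structures the sphere
#' parameters are retained in `spheres` so that masks can be regenerated
#' exactly on a supersampled grid instead of being resampled.
#'
#' @param masks Named list of logical arrays, all with the grid's dimensions.
#' @param grid The reference [dose_grid()] (only geometry is used).
#' @param spheres Optional named list of `list(center =, radius =)` (mm)
#'   describing structures that are exact spheres.
#' @return An object of class `structure_set` with `masks`, `voxel_volume`
#'   (mm^3), grid geometry, and `spheres`.
#' @export
structure_set <- function(masks, grid, spheres = NULL) {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  dims <- dim(grid$values)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dims)) {
      stop("mask '", nm, "' is not congruent with the dose grid", call. = FALSE)
    }
  }
  structure(
    list(masks = masks, voxel_volume = prod(grid$spacing),
         origin = grid$origin, spacing = grid$spacing, dim = dims,
         spheres = spheres),
    class = "structure_set"
  )
}

#' Structure volume from voxel counting
#' @param structures A [structure_set()].
#' @param name Structure name.
#' @return Volume in mm^3.
#' @export
structure_volume <- function(structures, name) {
  sum(structures$masks[[name]]) * structures$voxel_volume
}

# Linear indices of a mask's TRUE voxels plus its index bounding box,
# used by the fast masked-shift sampler.
.mask_index <- function(mask) {
  idx <- which(mask)
  d <- dim(mask)
  ijk <- arrayInd(idx, d)
  list(lin = idx, ijk = ijk, dim = d,
       lo = apply(ijk, 2, min), hi = apply(ijk, 2, max))
}
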