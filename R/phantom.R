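#' Spherical cranial phantom specification
#'
#' Describes a homogeneous, water-equivalent spherical head phantom with a
#' single spherical gross tumour volume (GTV) at its centre. The planning
#' target volume (PTV) is the GTV expanded isotropically by `ptv_margin`;
#' for spheres this dilation is exact (radius + margin). The dose grid is
#' cubic, centred on the GTV centroid (the isocenter), with an odd voxel
#' count per axis so the isocenter falls on a voxel centre.
#'
#' @param gtv_radius GTV radius (mm).
#' @param ptv_margin Isotropic GTV-to-PTV margin (mm), default 2.
#' @param grid_spacing Isotropic dose-grid spacing (mm), default 1.5.
#' @param grid_extent Full grid width per axis (mm). `NULL` (default) sizes
#'   the grid to the PTV radius plus 12.5 mm, covering the 3.5 mm motion cap
#'   and the dose penumbra with margin to spare.
#' @param head_radius Radius of the water-equivalent head sphere (mm),
#'   centred on the isocenter; default 80. Must enclose the grid region of
#'   interest.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(gtv_radius, ptv_margin = 2, grid_spacing = 1.5,
                         grid_extent = NULL, head_radius = 80) {
  stopifnot(gtv_radius > 0, ptv_margin >= 0, grid_spacing > 0,
            head_radius > gtv_radius + ptv_margin)
  if (is.null(grid_extent)) {
    grid_extent <- 2 * (gtv_radius + ptv_margin + 12.5)
  }
  if (grid_extent < 2 * (gtv_radius + ptv_margin + 5)) {
    stop("grid_extent leaves less than 5 mm clearance beyond the PTV",
         call. = FALSE)
  }
  structure(
    list(gtv_radius = gtv_radius, ptv_margin = ptv_margin,
         grid_spacing = grid_spacing, grid_extent = grid_extent,
         head_radius = head_radius),
    class = "phantom_spec"
  )
}

# Logical sphere mask from axis coordinate vectors (voxel-centre test).
.sphere_mask <- function(xs, ys, zs, center, radius) {
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Build the phantom dose grid and structure set
#'
#' Materialises a [phantom_spec()] into an empty [dose_grid()] template and
#' a [structure_set()] holding GTV and PTV masks. Masks are voxel-centre
#' tests against the analytic spheres; the sphere parameters are stored so
#' supersampling can regenerate them exactly.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `grid` (empty [dose_grid()]), `structures`
#'   (a [structure_set()]) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$grid_spacing
  half_n <- ceiling(spec$grid_extent / 2 / h)
  n <- 2L * half_n + 1L
  coords <- (seq_len(n) - 1 - half_n) * h
  values <- array(0, dim = c(n, n, n))
  grid <- dose_grid(values, origin = rep(coords[1], 3), spacing = h)
  r_ptv <- spec$gtv_radius + spec$ptv_margin
  spheres <- list(
    GTV = list(center = c(0, 0, 0), radius = spec$gtv_radius),
    PTV = list(center = c(0, 0, 0), radius = r_ptv)
  )
  masks <- lapply(spheres, function(s) {
    .sphere_mask(coords, coords, coords, s$center, s$radius)
  })
  structures <- structure_set(masks, grid, spheres = spheres)
  list(grid = grid, structures = structures, spec = spec)
}
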