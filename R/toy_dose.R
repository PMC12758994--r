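#' Analytic dose-engine parameters
#'
#' Parameters of the package's analytic dose model for a homogeneous,
#' water-equivalent head: the jaw-clipped MLC aperture is projected
#' divergently from the source through the isocenter plane, blurred by a
#' Gaussian lateral penumbra, and attenuated exponentially with depth from
#' the head surface along each ray.
#'
#' @param mu_attenuation Effective linear attenuation coefficient
#'   (per mm), default 0.005 (megavoltage beam in water).
#' @param penumbra_sigma Gaussian penumbra sigma in the isocenter plane
#'   (mm), default 3.
#' @param source_axis_distance Source-to-isocenter distance (mm),
#'   default 1000.
#' @param fluence_pixel Pixel size of the internal fluence raster (mm),
#'   default 0.5.
#' @return An object of class `toy_dose_params`.
#' @export
toy_dose_params <- function(mu_attenuation = 0.005, penumbra_sigma = 3,
                            source_axis_distance = 1000,
                            fluence_pixel = 0.5) {
  stopifnot(mu_attenuation > 0, penumbra_sigma > 0,
            source_axis_distance > 0, fluence_pixel > 0)
  structure(
    list(mu_attenuation = mu_attenuation, penumbra_sigma = penumbra_sigma,
         source_axis_distance = source_axis_distance,
         fluence_pixel = fluence_pixel),
    class = "toy_dose_params"
  )
}

# Rasterize the jaw-clipped MLC aperture of a control point onto a square
# pixel grid in the isocenter plane (x = leaf travel, y = pair stack).
# Returns list(x, y, z) with z[i, j] in {0, 1}; pixels whose centre lies in
# the open window of some pair are 1. Used both for the fluence model and,
# at fine pixel size, as an area cross-check.
.rasterize_aperture <- function(cp, mlc, pixel, pad = 0) {
  j <- cp$jaws
  lo <- mlc$leaf_edges[-(mlc$n_pairs + 1)]
  hi <- mlc$leaf_edges[-1]
  a <- pmax(cp$bank_a, j[["x1"]])
  b <- pmin(cp$bank_b, j[["x2"]])
  ylo <- pmax(lo, j[["y1"]])
  yhi <- pmin(hi, j[["y2"]])
  open <- which(b > a & yhi > ylo)
  if (length(open) == 0) {
    x <- seq(-pad - pixel, pad + pixel, by = pixel)
    return(list(x = x, y = x, z = matrix(0, length(x), length(x))))
  }
  xr <- range(a[open], b[open]) + c(-pad, pad)
  yr <- range(ylo[open], yhi[open]) + c(-pad, pad)
  x <- seq(xr[1], xr[2], by = pixel)
  y <- seq(yr[1], yr[2], by = pixel)
  z <- matrix(0, length(x), length(y))
  for (p in open) {
    ix <- which(x > a[p] & x < b[p])
    iy <- which(y > ylo[p] & y < yhi[p])
    z[ix, iy] <- 1
  }
  list(x = x, y = y, z = z)
}

# Dense Gaussian blur matrix for coordinates xs (uniform spacing), sigma in
# the same units; rows renormalized so a flat field stays flat.
.blur_matrix <- function(xs, sigma) {
  k <- outer(xs, xs, function(u, v) stats::dnorm(u - v, sd = sigma))
  k / rowSums(k)
}

# Bilinear interpolation of matrix z (on uniform axes x, y) at query points
# (qx, qy); zero outside the raster.
.bilinear <- function(x, y, z, qx, qy) {
  nx <- length(x); ny <- length(y)
  hx <- x[2] - x[1]; hy <- y[2] - y[1]
  fx <- (qx - x[1]) / hx
  fy <- (qy - y[1]) / hy
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  ok <- i0 >= 0 & i0 <= nx - 2 & j0 >= 0 & j0 <= ny - 2
  out <- numeric(length(qx))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; wx <- wx[ok]; wy <- wy[ok]
  base <- i0 + 1 + j0 * nx
  out[ok] <- z[base] * (1 - wx) * (1 - wy) +
    z[base + 1] * wx * (1 - wy) +
    z[base + nx] * (1 - wx) * wy +
    z[base + nx + 1] * wx * wy
  out
}

#' Dose of one static control-point field
#'
#' Computes the 3D dose deposited by a single control point treated as a
#' static field: the jaw-clipped MLC aperture is rasterized in the isocenter
#' plane, blurred with the Gaussian penumbra, projected divergently from the
#' source, and attenuated exponentially with the radiological depth from the
#' head-sphere surface along each source-to-voxel ray. The result scales
#' linearly with `mu_weight` and with `rx_dose`; the absolute level is fixed
#' afterwards by [normalize_plan_dose()]. Deterministic given its inputs.
#'
#' Geometry: patient-fixed right-handed axes (mm). The gantry rotates in the
#' x-y plane; at angle theta the beam axis unit vector is
#' `(sin theta, -cos theta, 0)`, leaf travel is along
#' `(cos theta, sin theta, 0)` and the leaf stack along patient z.
#'
#' @param cp A [control_point()].
#' @param phantom A phantom as returned by [make_phantom()].
#' @param params A [toy_dose_params()].
#' @param rx_dose Prescription dose used as the linear dose scale (Gy).
#' @param mlc An [mlc_model()].
#' @return A [dose_grid()] congruent with the phantom grid.
#' @export
compute_cp_dose <- function(cp, phantom, params = toy_dose_params(),
                            rx_dose = 1, mlc = hd120_mlc()) {
  stopifnot(inherits(cp, "control_point"), inherits(params, "toy_dose_params"))
  grid <- phantom$grid
  dims <- dim(grid$values)
  out <- array(0, dim = dims)
  amp <- cp$mu_weight * rx_dose
  if (amp == 0) return(dose_grid(out, grid$origin, grid$spacing))

  sig <- params$penumbra_sigma
  ras <- .rasterize_aperture(cp, mlc, params$fluence_pixel, pad = 4 * sig)
  if (all(ras$z == 0)) return(dose_grid(out, grid$origin, grid$spacing))
  kx <- .blur_matrix(ras$x, sig)
  ky <- .blur_matrix(ras$y, sig)
  fl <- kx %*% ras$z %*% t(ky)

  th <- cp$gantry_angle * pi / 180
  u <- c(sin(th), -cos(th), 0)           # beam axis (source -> isocenter)
  e1 <- c(cos(th), sin(th), 0)           # leaf travel in BEV
  sad <- params$source_axis_distance

  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  X <- array(xs, dims)
  Y <- array(rep(ys, each = dims[1]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

  pu <- X * u[1] + Y * u[2]              # u has zero z-component
  t_ax <- sad + pu                       # distance from source along axis
  mag <- sad / t_ax
  xb <- (X * e1[1] + Y * e1[2]) * mag
  yb <- Z * mag
  f <- array(.bilinear(ras$x, ras$y, fl, as.vector(xb), as.vector(yb)), dims)

  # depth from head-sphere surface (radius R about the isocenter) to the
  # voxel along the source-to-voxel ray
  r_head <- phantom$spec$head_radius
  sx <- -sad * u[1]; sy <- -sad * u[2]
  dxv <- X - sx; dyv <- Y - sy; dzv <- Z
  dist <- sqrt(dxv^2 + dyv^2 + dzv^2)
  sdotd <- (sx * dxv + sy * dyv) / dist
  disc <- sdotd^2 - (sad^2 - r_head^2)
  inside <- disc > 0
  depth <- array(0, dims)
  tau <- -sdotd[inside] - sqrt(disc[inside])
  depth[inside] <- pmax(0, dist[inside] - tau)
  hit <- inside & (X^2 + Y^2 + Z^2 <= r_head^2)

  dose <- array(0, dims)
  dose[hit] <- amp * f[hit] * exp(-params$mu_attenuation * depth[hit])
  dose_grid(dose, grid$origin, grid$spacing)
}

#' Dose grids of every control point of a plan
#'
#' @param plan A [plan_spec()].
#' @param phantom A phantom as returned by [make_phantom()].
#' @param params A [toy_dose_params()].
#' @param mlc An [mlc_model()].
#' @return List of [dose_grid()], one per control point, in delivery order.
#' @export
compute_plan_dose <- function(plan, phantom, params = toy_dose_params(),
                              mlc = hd120_mlc()) {
  lapply(plan$control_points, compute_cp_dose, phantom = phantom,
         params = params, rx_dose = plan$rx_dose, mlc = mlc)
}

#' Sum a list of congruent dose grids
#' @param cp_doses List of [dose_grid()] on a common grid.
#' @return A [dose_grid()] holding the voxelwise sum.
#' @export
sum_dose <- function(cp_doses) {
  stopifnot(length(cp_doses) >= 1)
  acc <- cp_doses[[1]]$values
  for (i in seq_along(cp_doses)[-1]) acc <- acc + cp_doses[[i]]$values
  dose_grid(acc, cp_doses[[1]]$origin, cp_doses[[1]]$spacing)
}

#' Normalize a plan's dose to a target PTV coverage
#'
#' Finds the scalar factor to apply to every control-point dose so that the
#' static cumulative dose covers the PTV at the clinical goal
#' `V_Rx = target_vrx` (percent of PTV receiving at least the prescription).
#' Coverage is evaluated exactly as the scenario metrics evaluate it: on the
#' fivefold supersampled cumulative grid with analytically regenerated
#' masks. The factor is located by bisection on the monotone coverage step
#' function until the bracket collapses (relative 1e-13), landing on the
#' smallest factor reaching the target; the achieved coverage must fall
#' within `tol` percentage points of the target or an error is raised.
#' Renormalizing an already-normalized plan therefore returns 1 to within
#' the bracket tolerance.
#'
#' @param cp_doses List of per-control-point [dose_grid()].
#' @param structures A [structure_set()].
#' @param rx_dose Prescription dose (Gy).
#' @param target_vrx Target PTV coverage (percent), default 99.
#' @param tol Coverage tolerance (percentage points), default 0.1.
#' @param supersample_factor Supersampling factor used for the coverage
#'   evaluation, default 5.
#' @return The scale factor (numeric scalar).
#' @export
normalize_plan_dose <- function(cp_doses, structures, rx_dose,
                                target_vrx = 99, tol = 0.1,
                                supersample_factor = 5) {
  static <- sum_dose(cp_doses)
  fine <- supersample(static, supersample_factor)
  fmask <- supersample_structures(structures, static, supersample_factor)
  vals <- fine$values[fmask$masks[["PTV"]]]
  if (length(vals) == 0 || max(vals) <= 0) {
    stop("cannot normalize: PTV is empty or receives no dose", call. = FALSE)
  }
  vrx_of <- function(k) 100 * mean(k * vals >= rx_dose)
  lo <- rx_dose / max(vals)              # vrx just > 0
  hi <- rx_dose / min(vals[vals > 0]) * 2
  if (vrx_of(hi) < target_vrx) hi <- hi * 1e3
  if (vrx_of(hi) < target_vrx) {
    stop("cannot normalize: target V_Rx unattainable", call. = FALSE)
  }
  while ((hi - lo) > 1e-13 * hi) {
    mid <- (lo + hi) / 2
    if (vrx_of(mid) < target_vrx) lo <- mid else hi <- mid
  }
  if (abs(vrx_of(hi) - target_vrx) > tol) {
    stop("cannot normalize: coverage step exceeds the tolerance around the target",
         call. = FALSE)
  }
  hi
}

#' Apply a scalar factor to a list of dose grids
#' @param cp_doses List of [dose_grid()].
#' @param k Scale factor.
#' @return List of scaled [dose_grid()].
#' @export
scale_dose <- function(cp_doses, k) {
  lapply(cp_doses, function(g) dose_grid(g$values * k, g$origin, g$spacing))
}
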