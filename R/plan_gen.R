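#' Generate a synthetic single-target VMAT plan
#'
#' Builds a VMAT-like plan for a spherical-target phantom. Gantry angles are
#' evenly spaced at `cp_spacing` degrees within each arc (full arcs starting
#' at staggered angles, truncated to `cps_per_arc`). At each control point
#' the MLC aperture starts from the conformal beam's-eye-view outline of the
#' PTV sphere (per leaf pair, the silhouette half-chord at the pair's least
#' off-axis extent) and is then modulated the way VMAT optimizers modulate
#' real apertures, with a sliding sub-window:
#'
#' * a per-control-point factor `s` is drawn from a mean-one log-normal with
#'   coefficient of variation `modulation_cv`;
#' * `s < 1` keeps a window of fractional width `s` placed at a uniformly
#'   random position inside the conformal opening of every pair (so small
#'   apertures present leaf edges inside the target projection, as clinical
#'   sliding-window segments do);
#' * `s >= 1` opens every pair symmetrically beyond conformal by the factor
#'   `s`, clipped to the jaw window.
#'
#' With `modulation_cv = 0` every aperture is exactly conformal. Monitor-unit
#' weights are uniform with symmetric Dirichlet jitter
#' (concentration `mu_concentration`), normalized to sum to one. Jaws are
#' fixed per plan at the PTV silhouette plus 5 mm.
#'
#' @param n_arcs Number of arcs.
#' @param cps_per_arc Control points per arc (>= 2).
#' @param rx_dose Total prescription dose (Gy).
#' @param n_fractions Number of fractions.
#' @param phantom Phantom from [make_phantom()].
#' @param rng_seed Integer seed governing apertures and MU jitter.
#' @param cp_spacing Gantry spacing (degrees), default 2.
#' @param modulation_cv Coefficient of variation of the aperture modulation
#'   factor, default 0.3.
#' @param mu_concentration Dirichlet concentration of the MU jitter,
#'   default 50.
#' @param sad Source-axis distance used for the silhouette magnification
#'   (mm), default 1000.
#' @param mlc An [mlc_model()].
#' @param plan_id Identifier; default derived from the seed.
#' @return A [plan_spec()].
#' @export
make_plan <- function(n_arcs, cps_per_arc, rx_dose, n_fractions, phantom,
                      rng_seed, cp_spacing = 2, modulation_cv = 0.3,
                      mu_concentration = 50, sad = 1000, mlc = hd120_mlc(),
                      plan_id = NULL) {
  stopifnot(cps_per_arc >= 2, n_arcs >= 1)
  if (is.null(plan_id)) plan_id <- sprintf("synthetic-%d", rng_seed)
  set.seed(rng_seed)
  n_cps <- n_arcs * cps_per_arc

  r_ptv <- phantom$spec$gtv_radius + phantom$spec$ptv_margin
  # silhouette of a sphere centred at isocenter, projected to the
  # isocenter plane
  rs <- r_ptv * sad / sqrt(sad^2 - r_ptv^2)
  jaw <- c(x1 = -(rs + 5), x2 = rs + 5, y1 = -(rs + 5), y2 = rs + 5)

  lo <- mlc$leaf_edges[-(mlc$n_pairs + 1)]
  hi <- mlc$leaf_edges[-1]
  # least |y| inside each pair's stack interval: 0 if the pair straddles
  # the axis, else the nearer edge
  ymin <- pmin(abs(lo), abs(hi))
  ymin[lo < 0 & hi > 0] <- 0
  half <- ifelse(ymin < rs, sqrt(pmax(rs^2 - ymin^2, 0)), 0)

  angles <- unlist(lapply(seq_len(n_arcs), function(a) {
    (a - 1) * 360 / n_arcs + (seq_len(cps_per_arc) - 1) * cp_spacing
  })) %% 360

  sdlog <- sqrt(log(1 + modulation_cv^2))
  s_fac <- if (modulation_cv > 0) {
    exp(stats::rnorm(n_cps, -sdlog^2 / 2, sdlog))
  } else {
    rep(1, n_cps)
  }
  pos <- stats::runif(n_cps)
  w <- stats::rgamma(n_cps, shape = mu_concentration, rate = 1)
  w <- w / sum(w)

  cps <- vector("list", n_cps)
  for (i in seq_len(n_cps)) {
    s <- s_fac[i]
    if (s < 1) {
      shift <- pos[i] * (1 - s) * 2 * half
      a <- -half + shift
      b <- a + s * 2 * half
    } else {
      a <- pmax(-half * s, jaw[["x1"]])
      b <- pmin(half * s, jaw[["x2"]])
    }
    closed <- half == 0
    a[closed] <- 0
    b[closed] <- 0
    cps[[i]] <- control_point(index = i - 1L, gantry_angle = angles[i],
                              mu_weight = w[i], bank_a = a, bank_b = b,
                              jaws = jaw)
  }
  plan_spec(plan_id = plan_id, rx_dose = rx_dose, n_fractions = n_fractions,
            n_arcs = n_arcs, control_points = cps, cp_spacing = cp_spacing)
}
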