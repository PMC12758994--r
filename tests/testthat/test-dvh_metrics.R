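test_that("supersampling is the identity at factor 1 and exact on linear fields", {
  g <- ramp_grid(n = 9, spacing = 3)
  expect_identical(supersample(g, 1), g)

  # purely linear field (no cross terms): trilinear interpolation is exact
  n <- 9
  xs <- (seq_len(n) - 5) * 3
  v <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    v[, , k] <- outer(xs, xs, function(a, b) 5 + 0.2 * a - 0.1 * b) +
      0.05 * xs[k]
  }
  lin <- dose_grid(v, rep(xs[1], 3), 3)
  fine <- supersample(lin, 4)
  fx <- grid_axis(fine, 1)
  expect_equal(dim(fine$values), rep((n - 1) * 4 + 1, 3))
  expect_equal(fine$spacing, rep(3 / 4, 3))
  i <- 7; j <- 12; k <- 22
  expect_equal(fine$values[i, j, k],
               5 + 0.2 * fx[i] - 0.1 * fx[j] + 0.05 * fx[k],
               tolerance = 1e-12)
})

test_that("supersampling reduces the DVH discretization error of a uniform-dose sphere", {
  ph <- make_phantom(phantom_spec(7, 2, 1.5))
  # uniform 10 Gy inside an 8 mm sphere crossing the 9 mm PTV; the analytic
  # V(5 Gy) of the PTV is the volume ratio (8/9)^3
  g <- ph$grid
  r <- sqrt(outer(outer(grid_axis(g, 1)^2, grid_axis(g, 2)^2, `+`),
                  grid_axis(g, 3)^2, `+`))
  dose <- dose_grid(array(10 * (r <= 8), dim(g$values)), g$origin, g$spacing)
  frac_err <- function(factor) {
    d <- supersample(dose, factor)
    m <- supersample_structures(ph$structures, dose, factor)
    abs(mean(d$values[m$masks$PTV] >= 5) - (8 / 9)^3)
  }
  expect_lte(frac_err(5), frac_err(1))
})

test_that("cumulative DVH closed forms and sort-based oracle agree", {
  # uniform dose on the mask
  g <- dose_grid(array(7, c(4, 4, 4)), 0, 1)
  mask <- array(TRUE, c(4, 4, 4))
  dvh <- compute_dvh(g, mask)
  expect_equal(dvh$volume_fraction[1], 100)
  expect_true(all(dvh$volume_fraction == 100))
  expect_equal(v_at_dose(dvh, 3.5), 100)
  expect_equal(v_at_dose(dvh, 14), 0)
  expect_equal(dvh_auc(dvh), 7, tolerance = 1e-12)

  # two voxels at 1 and 3 Gy
  v2 <- array(0, c(2, 1, 1)); v2[1] <- 1; v2[2] <- 3
  g2 <- dose_grid(v2, 0, 1)
  dvh2 <- compute_dvh(g2, array(TRUE, c(2, 1, 1)))
  expect_equal(v_at_dose(dvh2, 2), 50, tolerance = 0.2)
  expect_equal(d_at_volume(dvh2, 50), 3, tolerance = 0.01)
  expect_equal(dvh_auc(dvh2), 2, tolerance = 0.01)

  # random fields against direct counting at every edge
  set.seed(33)
  for (rep in 1:5) {
    vals <- rgamma(400, 2, 0.5)
    arr <- array(vals, c(400, 1, 1))
    m <- array(TRUE, c(400, 1, 1))
    dvh <- compute_dvh(dose_grid(arr, 0, 1), m)
    expect_equal(dvh$volume_fraction, oracle_dvh(vals, dvh$dose))
    # curves are monotone non-increasing in [0, 100]
    expect_true(all(diff(dvh$volume_fraction) <= 0))
    expect_true(all(dvh$volume_fraction >= 0 & dvh$volume_fraction <= 100))
    # AUC equals the mean dose within one bin width
    expect_lt(abs(dvh_auc(dvh) - mean(vals)), dvh$dose[2] - dvh$dose[1])
    # V at a dose matches the direct count within bin resolution
    q <- quantile(vals, 0.3)
    expect_lt(abs(v_at_dose(dvh, q) - 100 * mean(vals >= q)), 0.5)
    # D at a volume matches the order-statistic oracle within one bin
    d99 <- d_at_volume(dvh, 99)
    expect_lt(abs(100 * mean(vals >= d99) - 99), 1)
  }

  expect_error(compute_dvh(g, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("DVH metrics are monotone under pointwise dose domination", {
  set.seed(12)
  lo_vals <- rgamma(300, 3, 1)
  hi_vals <- lo_vals + rexp(300, 2)
  m <- array(TRUE, c(300, 1, 1))
  glo <- dose_grid(array(lo_vals, c(300, 1, 1)), 0, 1)
  ghi <- dose_grid(array(hi_vals, c(300, 1, 1)), 0, 1)
  bw <- max(hi_vals) / 1000
  dlo <- compute_dvh(glo, m, bin_width = bw, max_dose = max(hi_vals))
  dhi <- compute_dvh(ghi, m, bin_width = bw, max_dose = max(hi_vals))
  q <- median(lo_vals)
  expect_gte(v_at_dose(dhi, q), v_at_dose(dlo, q))
  expect_gte(d_at_volume(dhi, 99), d_at_volume(dlo, 99))
})

test_that("cp AUC metrics: zero motion, hand-computed two-trace case, antisymmetric pair", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 4, seed = 3)
  cpd <- compute_plan_dose(plan, ph)
  n <- length(cpd)

  zeros <- lapply(1:3, function(i) make_trace(matrix(0, n, 3), id = i))
  m0 <- cp_auc_metrics(cpd, zeros, ph$structures, plan = plan)
  expect_equal(m0$mauc_mgy, rep(0, n))
  expect_equal(m0$sauc_mgy, rep(0, n))
  expect_false(any(m0$sensitive))
  expect_equal(m0$aperture_area_mm2,
               vapply(plan$control_points, aperture_area, numeric(1)))

  expect_error(cp_auc_metrics(cpd, zeros[1], ph$structures), "2 motion traces")

  # single control point, one-voxel PTV, two traces of one voxel spacing:
  # shifted AUCs are the neighbouring voxel values, so mAUC/sAUC follow by
  # two-point arithmetic
  g <- ramp_grid(n = 9, spacing = 1.5)
  mask <- array(FALSE, c(9, 9, 9)); mask[5, 5, 5] <- TRUE
  structs <- structure_set(list(PTV = mask), g)
  tr1 <- make_trace(matrix(c(1.5, 0, 0), 1, 3), "a")
  tr2 <- make_trace(matrix(c(-1.5, 0, 0), 1, 3), "b")
  rec <- cp_auc_metrics(list(g), list(tr1, tr2), structs)
  d0 <- g$values[5, 5, 5]
  diffs <- c(g$values[6, 5, 5] - d0, g$values[4, 5, 5] - d0) * 1000
  bw_mgy <- max(g$values) / 2000 * 1000
  expect_lt(abs(rec$mauc_mgy - mean(diffs)), 2 * bw_mgy)
  expect_lt(abs(rec$sauc_mgy - sd(diffs)), 2 * bw_mgy)

  # symmetric +/- displacements on a linear gradient: mAUC ~ 0, sAUC > 0
  expect_gt(rec$sauc_mgy, 0)
})

test_that("scenario metrics: identity scenario and dose-scaling homogeneity", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 12, seed = 23)
  cpd <- compute_plan_dose(plan, ph)
  k <- normalize_plan_dose(cpd, ph$structures, plan$rx_dose,
                           supersample_factor = 3)
  cpd <- scale_dose(cpd, k)
  static <- sum_dose(cpd)

  scaled <- dose_grid(static$values * 1.01, static$origin, static$spacing)
  sm <- scenario_metrics(static, list(static, scaled), ph$structures,
                         plan$rx_dose, supersample_factor = 3)
  expect_equal(sm$delta_vrx[1], 0)
  expect_equal(sm$delta_d99_pct[1], 0)
  expect_equal(sm$delta_d99_pct[2], 1, tolerance = 0.15)
  expect_gte(sm$delta_vrx[2], 0)
  expect_true(all(sm$vrx >= 0 & sm$vrx <= 100))
})
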