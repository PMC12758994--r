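test_that("phantom masks: analytic sphere volume, identity margin, containment", {
  ph <- make_phantom(phantom_spec(10, 2, 1.5))
  v_analytic <- 4 / 3 * pi * 12^3
  v_count <- structure_volume(ph$structures, "PTV")
  # voxel-centre counting at 1.5 mm carries a surface discretization error
  # of order a percent for this radius
  expect_lt(abs(v_count - v_analytic) / v_analytic, 0.02)
  expect_true(all(ph$structures$masks$PTV[ph$structures$masks$GTV]))

  ph0 <- make_phantom(phantom_spec(10, 0, 1.5))
  expect_identical(ph0$structures$masks$PTV, ph0$structures$masks$GTV)

  # reference-case scale: 8.8 mm GTV + 2 mm margin gives a ~5.24 cc PTV
  ph19 <- make_phantom(phantom_spec(8.8, 2, 1.5))
  expect_lt(abs(structure_volume(ph19$structures, "PTV") / 1000 - 5.24), 0.2)

  expect_error(phantom_spec(10, 2, 1.5, grid_extent = 20), "clearance")
})

test_that("generated plans are well-formed for any seed and conformal at zero noise", {
  ph <- tiny_phantom()
  for (seed in c(1, 99)) {
    plan <- make_plan(3, 10, 25, 5, ph, rng_seed = seed)
    expect_length(validate_plan(plan), 0)
    expect_equal(length(plan$control_points), 30)
  }
  plan0 <- make_plan(1, 16, 25, 5, ph, rng_seed = 5, modulation_cv = 0)
  areas <- vapply(plan0$control_points, aperture_area, numeric(1))
  # spherical target at isocenter: the conformal projection is the same at
  # every gantry angle
  expect_lt(diff(range(areas)) / mean(areas), 1e-10)
  # per-pair conformality circumscribes the silhouette disc: the staircase
  # area sits above the disc but within the circumscribed-step bound
  expect_gte(mean(areas), pi * 8^2)
  expect_lte(mean(areas), 1.4 * pi * 8^2)
})

test_that("aperture areas across a modulated plan have the configured variation and right skew", {
  ph <- tiny_phantom()
  plan <- make_plan(2, 150, 25, 5, ph, rng_seed = 3, modulation_cv = 0.3)
  areas <- vapply(plan$control_points, aperture_area, numeric(1))
  cv <- sd(areas) / mean(areas)
  expect_gt(cv, 0.18)
  expect_lt(cv, 0.45)
  skew <- mean((areas - mean(areas))^3) / sd(areas)^3
  expect_gt(skew, 0)
})

test_that("control-point dose: closed aperture, linearity in mu_weight", {
  ph <- tiny_phantom()
  closed <- control_point(0, 10, 0.5, bank_a = rep(0, 60), bank_b = rep(0, 60))
  z <- compute_cp_dose(closed, ph, rx_dose = 25)
  expect_true(all(z$values == 0))

  open <- control_point(0, 40, 0.1, bank_a = rep(-8, 60), bank_b = rep(8, 60))
  d1 <- compute_cp_dose(open, ph, rx_dose = 25)
  open2 <- open; open2$mu_weight <- 0.2
  d2 <- compute_cp_dose(open2, ph, rx_dose = 25)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  expect_gt(max(d1$values), 0)
})

test_that("on-axis depth-dose follows the exponential attenuation closed form", {
  ph <- make_phantom(phantom_spec(8, 2, 1.5))
  params <- toy_dose_params(mu_attenuation = 0.006)
  # anterior beam (gantry 0): beam axis is -y, on-axis voxels have x = z = 0
  cp <- control_point(0, 0, 1, bank_a = rep(-10, 60), bank_b = rep(10, 60))
  d <- compute_cp_dose(cp, ph, params, rx_dose = 1)
  n <- dim(d$values)[1]
  c0 <- (n + 1) / 2
  ys <- grid_axis(d, 2)
  i1 <- c0 + 5; i2 <- c0 - 5          # shallower (+y) and deeper (-y)
  ratio <- d$values[c0, i2, c0] / d$values[c0, i1, c0]
  expect_equal(ratio, exp(-0.006 * (ys[i1] - ys[i2])), tolerance = 1e-6)
})

test_that("normalization hits the coverage goal, scales homogeneously, and is idempotent", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 24, seed = 21)
  cpd <- compute_plan_dose(plan, ph)
  k <- normalize_plan_dose(cpd, ph$structures, plan$rx_dose)
  cpd_n <- scale_dose(cpd, k)
  fine <- supersample(sum_dose(cpd_n), 5)
  fmask <- supersample_structures(ph$structures, sum_dose(cpd_n), 5)
  vrx <- 100 * mean(fine$values[fmask$masks$PTV] >= plan$rx_dose)
  expect_gte(vrx, 98.9)
  expect_lte(vrx, 99.1)

  k2 <- normalize_plan_dose(cpd_n, ph$structures, plan$rx_dose)
  expect_equal(k2, 1, tolerance = 1e-6)

  # rescaling dose by c rescales the DVH dose axis by c
  dvh1 <- compute_dvh(sum_dose(cpd_n), ph$structures$masks$PTV)
  dvh2 <- compute_dvh(sum_dose(scale_dose(cpd_n, 2)), ph$structures$masks$PTV)
  expect_equal(dvh2$dose, 2 * dvh1$dose, tolerance = 1e-12)
  expect_equal(dvh2$volume_fraction, dvh1$volume_fraction)

  empty <- dose_grid(array(0, dim(ph$grid$values)), ph$grid$origin,
                     ph$grid$spacing)
  expect_error(normalize_plan_dose(list(empty), ph$structures, 25),
               "normalize")
})

test_that("plan archive round-trips plans and phantoms losslessly", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 8, seed = 13)
  dir <- withr::local_tempdir()
  write_plan_archive(dir, plan, phantom = ph)
  back <- read_plan_archive(dir)
  expect_equal(back$plan$rx_dose, plan$rx_dose)
  expect_equal(length(back$plan$control_points), 8)
  expect_equal(back$plan$control_points[[3]]$bank_a,
               plan$control_points[[3]]$bank_a)
  expect_equal(back$plan$control_points[[3]]$jaws,
               plan$control_points[[3]]$jaws)
  expect_equal(back$phantom$structures$masks$PTV, ph$structures$masks$PTV)
  expect_length(validate_plan(back$plan), 0)
})
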