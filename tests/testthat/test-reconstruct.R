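test_that("zero shift is the identity and integer-voxel shifts are index rolls", {
  g <- ramp_grid(n = 13, spacing = 2)
  expect_equal(shift_dose(g, c(0, 0, 0))$values, g$values, tolerance = 1e-15)

  # +one voxel spacing along x: output samples input at x + dx, an index
  # roll with the trailing slab zeroed
  s <- shift_dose(g, c(2, 0, 0))
  expected <- array(0, dim(g$values))
  expected[1:12, , ] <- g$values[2:13, , ]
  expect_equal(s$values, expected, tolerance = 1e-14)

  s2 <- shift_dose(g, c(0, -4, 0))
  expected2 <- array(0, dim(g$values))
  expected2[, 3:13, ] <- g$values[, 1:11, ]
  expect_equal(s2$values, expected2, tolerance = 1e-14)

  expect_error(shift_dose(g, c(NA, 0, 0)), "finite")
})

test_that("shifting by d then -d recovers the interior within interpolation tolerance", {
  g <- ramp_grid(n = 17, spacing = 2)
  d <- c(1.3, -0.7, 2.2)
  rt <- shift_dose(shift_dose(g, d), -d)
  interior <- 4:14
  err <- max(abs(rt$values[interior, interior, interior] -
                 g$values[interior, interior, interior]))
  expect_lt(err, 0.01 * max(g$values))
})

test_that("integral dose of a compactly supported field is conserved under shift", {
  # trilinear weights form a partition of unity, so a field whose support
  # stays clear of the boundary by more than the shift loses no integral
  ph <- tiny_phantom()
  cp <- control_point(0, 30, 0.3, bank_a = rep(-6, 60), bank_b = rep(6, 60))
  d <- compute_cp_dose(cp, ph, rx_dose = 25)
  xs <- grid_axis(d, 1)
  r <- sqrt(outer(outer(xs^2, xs^2, `+`), xs^2, `+`))
  inner <- dose_grid(d$values * (r <= max(xs) - 5), d$origin, d$spacing)
  s <- shift_dose(inner, c(1.7, -2.1, 0.9))
  expect_lt(abs(sum(s$values) - sum(inner$values)) / sum(inner$values), 1e-9)

  # for the full beam column the loss is confined to the boundary slabs it
  # crosses; the dose over the structures is untouched
  sfull <- shift_dose(d, c(1.7, -2.1, 0.9))
  ptv <- ph$structures$masks$PTV
  expect_gt(sum(sfull$values[ptv]), 0.9 * sum(d$values[ptv]))
})

test_that("scenario reconstruction: zero trace, one-hot plan, constant trace, permutation order", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 6, seed = 31)
  cpd <- compute_plan_dose(plan, ph)
  n <- length(cpd)

  zero <- make_trace(matrix(0, n, 3))
  sc <- reconstruct_scenario(cpd, zero)
  expect_identical(sc$cumulative$values, sum_dose(cpd)$values)

  # single nonzero control point: cumulative is that dose shifted
  one <- cpd
  for (i in 2:n) one[[i]] <- dose_grid(one[[i]]$values * 0, one[[i]]$origin,
                                       one[[i]]$spacing)
  tr <- make_trace(matrix(rep(c(1.1, 0.4, -0.8), each = n), n, 3))
  sc1 <- reconstruct_scenario(one, tr)
  expect_equal(sc1$cumulative$values,
               shift_dose(cpd[[1]], c(1.1, 0.4, -0.8))$values,
               tolerance = 1e-12)

  # constant trace: shift-then-sum equals sum-then-shift
  scc <- reconstruct_scenario(cpd, tr)
  direct <- shift_dose(sum_dose(cpd), c(1.1, 0.4, -0.8))
  expect_lt(max(abs(scc$cumulative$values - direct$values)),
            0.01 * max(direct$values))

  # permutation invariance in control-point order
  set.seed(8)
  dmat <- matrix(rnorm(3 * n, 0, 1), n, 3)
  perm <- sample(n)
  a <- reconstruct_scenario(cpd, make_trace(dmat))
  b <- reconstruct_scenario(cpd[perm], make_trace(dmat[perm, , drop = FALSE]))
  expect_equal(a$cumulative$values, b$cumulative$values, tolerance = 1e-12)

  expect_error(reconstruct_scenario(cpd, make_trace(matrix(0, n + 1, 3))),
               "control points")
})

test_that("coverage degrades monotonically as motion amplitude scales up", {
  ph <- tiny_phantom()
  plan <- tiny_plan(ph, cps = 30, seed = 17)
  cpd <- compute_plan_dose(plan, ph)
  k <- normalize_plan_dose(cpd, ph$structures, plan$rx_dose,
                           supersample_factor = 3)
  cpd <- scale_dose(cpd, k)
  static <- sum_dose(cpd)
  traces <- generate_batch(20, length(cpd), master_seed = 19)
  mean_vrx <- sapply(c(0, 0.5, 1, 2), function(sc) {
    cums <- lapply(traces, function(tr) {
      t2 <- tr; t2$displacements <- tr$displacements * sc
      reconstruct_scenario(cpd, t2)$cumulative
    })
    m <- scenario_metrics(static, cums, ph$structures, plan$rx_dose,
                          supersample_factor = 3)
    mean(m$vrx)
  })
  expect_true(all(diff(mean_vrx) <= 1e-9))
})
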