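# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (loops, sorting, pixel counting) and never call the
# implementation paths they check.

tiny_phantom <- function(gtv = 6, margin = 2, spacing = 1.5) {
  make_phantom(phantom_spec(gtv, margin, spacing))
}

tiny_plan <- function(phantom, n_arcs = 1, cps = 24, seed = 11, rx = 20,
                      fx = 5, cv = 0.3) {
  make_plan(n_arcs, cps, rx, fx, phantom, rng_seed = seed,
            modulation_cv = cv)
}

# Pixel-counting aperture area: counts pixel centres lying inside the jaw
# window, inside some pair's stack interval, and between that pair's leaf
# tips.
oracle_aperture_area <- function(cp, mlc, pixel = 0.05) {
  j <- cp$jaws
  xs <- seq(j[["x1"]] + pixel / 2, j[["x2"]], by = pixel)
  ys <- seq(j[["y1"]] + pixel / 2, j[["y2"]], by = pixel)
  edges <- mlc$leaf_edges
  total <- 0
  for (y in ys) {
    p <- findInterval(y, edges)
    if (p < 1 || p > mlc$n_pairs) next
    total <- total + sum(xs > cp$bank_a[p] & xs < cp$bank_b[p])
  }
  total * pixel^2
}

# Sort-free brute-force cumulative DVH: direct counting at each edge.
oracle_dvh <- function(vals, edges) {
  vapply(edges, function(e) 100 * sum(vals >= e) / length(vals), numeric(1))
}

# Welch t statistic, Satterthwaite dof and two-sided p, straight from the
# formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}

# Pearson r, Fisher-z 95% CI and t-based two-sided p, from the formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, ci = tanh(z + c(-1, 1) * qnorm(0.975) * se),
       p = 2 * pt(-abs(t), n - 2))
}

# A small dose grid holding an arbitrary smooth field, for shift/DVH tests.
ramp_grid <- function(n = 15, spacing = 2) {
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  v <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    v[, , k] <- outer(xs, xs, function(a, b) {
      10 + 0.1 * a - 0.05 * b + 0.02 * xs[k] + 0.001 * a * b
    })
  }
  dose_grid(v, origin = rep(xs[1], 3), spacing = spacing)
}

make_trace <- function(d_matrix, id = "t") {
  structure(list(displacements = d_matrix, trace_id = id, seed = NULL),
            class = "motion_trace")
}
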