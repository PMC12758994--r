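#' Intrafraction motion-model parameters
#'
#' Parameters of the 3D rigid intrafraction motion model for mask-immobilized
#' cranial patients. Defaults are the published per-axis displacement
#' distributions (mm): means (-0.072, -0.207, 0.195), standard deviations
#' (1.08, 1.06, 1.58), an initial-condition limit of 0.05 mm, and a hard
#' 3.5 mm cap on the 3D displacement magnitude. Treatment duration is
#' estimated from the gantry speed (6 deg/s) and control-point spacing
#' (2 deg) and drives the amplitude growth of the traces ("motion increases
#' with treatment duration").
#'
#' @param mean_xyz Per-axis mean end-of-treatment displacement (mm).
#' @param sd_xyz Per-axis standard deviation (mm).
#' @param init_limit Bound on each axis of the initial displacement (mm).
#' @param gantry_speed Gantry speed (deg/s).
#' @param cp_spacing Control-point spacing (deg).
#' @param cap_mm Maximum allowed 3D displacement magnitude (mm).
#' @param growth_exponent Exponent `g` of the `(t/T)^g` amplitude envelope;
#'   1 (default) ramps the displacement scale linearly in time.
#' @return An object of class `motion_model_params`.
#' @export
motion_model_params <- function(mean_xyz = c(-0.072, -0.207, 0.195),
                                sd_xyz = c(1.08, 1.06, 1.58),
                                init_limit = 0.05, gantry_speed = 6,
                                cp_spacing = 2, cap_mm = 3.5,
                                growth_exponent = 1) {
  stopifnot(length(mean_xyz) == 3, length(sd_xyz) == 3, all(sd_xyz >= 0),
            init_limit > 0, cap_mm > init_limit, gantry_speed > 0,
            cp_spacing > 0, growth_exponent >= 0)
  structure(
    list(mean_xyz = as.numeric(mean_xyz), sd_xyz = as.numeric(sd_xyz),
         init_limit = init_limit, gantry_speed = gantry_speed,
         cp_spacing = cp_spacing, cap_mm = cap_mm,
         growth_exponent = growth_exponent),
    class = "motion_model_params"
  )
}

#' Estimated treatment duration of an arc delivery
#'
#' `(n_cps - 1) * cp_spacing / gantry_speed` seconds; inter-arc gaps are
#' ignored (continuous delivery assumed).
#'
#' @param n_cps Number of control points (>= 2).
#' @param params A [motion_model_params()].
#' @return Duration in seconds.
#' @export
treatment_duration <- function(n_cps, params = motion_model_params()) {
  stopifnot(n_cps >= 2)
  (n_cps - 1) * params$cp_spacing / params$gantry_speed
}

#' Draw end-of-treatment displacement vectors
#'
#' Independent per-axis Gaussian draws from the published mean/SD; this is
#' the unmodulated displacement distribution at the end of treatment.
#'
#' @param params A [motion_model_params()].
#' @param n Number of draws.
#' @return `n x 3` matrix of displacements (mm), columns x, y, z.
#' @export
sample_endpoint <- function(params = motion_model_params(), n = 1) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3, byrow = TRUE)
  m <- sweep(m, 2, params$sd_xyz, `*`)
  m <- sweep(m, 2, params$mean_xyz, `+`)
  colnames(m) <- c("dx", "dy", "dz")
  m
}

#' Generate one control-point-indexed 3D motion trace
#'
#' Produces a continuous, time-evolved rigid displacement path sampled at
#' every control point. Per axis the construction is a Brownian bridge to a
#' random endpoint, wrapped in a growth envelope:
#'
#' * the start is uniform within the initial-condition limit and decays
#'   linearly;
#' * a standardized pinned-start Gaussian process `P(u)` (Brownian bridge
#'   plus `u` times a standard normal endpoint, so `P(0) = 0`,
#'   `P(1) ~ N(0, 1)`, `Var P(u) = u`) carries the stochastic part;
#' * the displacement is
#'   `d(u) = start * (1 - u) + mean * u^g + sd * u^(g - 1/2) * P(u)`
#'   with `u = t/T`, giving the marginal `N(mean * u^g, (sd * u^g)^2)` —
#'   the endpoint distribution modulated by the `(t/T)^g` amplitude
#'   envelope, and exactly [sample_endpoint()]'s distribution at `u = 1`.
#'
#' Finally any control point whose 3D magnitude exceeds `cap_mm` is
#' radially rescaled onto the cap, keeping the path continuous and the
#' batch size exact. No rotational components are modelled.
#'
#' @param n_cps Number of control points (>= 2).
#' @param params A [motion_model_params()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param trace_id Identifier stored on the trace.
#' @return An object of class `motion_trace`: list with `displacements`
#'   (`n_cps x 3` matrix, mm), `trace_id` and `seed`.
#' @export
generate_trace <- function(n_cps, params = motion_model_params(),
                           seed = NULL, trace_id = "trace") {
  stopifnot(n_cps >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n_cps
  u <- (seq_len(n) - 1) / (n - 1)
  g <- params$growth_exponent
  d <- matrix(0, n, 3)
  for (ax in 1:3) {
    m <- params$mean_xyz[ax]
    s <- params$sd_xyz[ax]
    start <- stats::runif(1, -params$init_limit, params$init_limit)
    eps <- stats::rnorm(1)
    inc <- stats::rnorm(n - 1, 0, sqrt(diff(u)))
    w <- c(0, cumsum(inc))
    p <- (w - u * w[n]) + u * eps        # pinned start, N(0, u) marginals
    env <- c(0, u[-1]^(g - 0.5))         # u = 0 handled explicitly
    d[, ax] <- start * (1 - u) + m * u^g + s * env * p
    d[1, ax] <- start
  }
  nrm <- sqrt(rowSums(d^2))
  over <- nrm > params$cap_mm
  if (any(over)) {
    # one-ulp shrink keeps the rescaled magnitude at or below the cap in
    # floating point
    d[over, ] <- d[over, ] * (params$cap_mm * (1 - 1e-12) / nrm[over])
  }
  colnames(d) <- c("dx", "dy", "dz")
  structure(list(displacements = d, trace_id = trace_id, seed = seed),
            class = "motion_trace")
}

#' Generate a reproducible batch of motion traces
#'
#' Child seeds are drawn deterministically from `master_seed`, so the same
#' master seed always reproduces the same batch bit for bit.
#'
#' @param n_traces Number of traces, default 100.
#' @param n_cps Control points per trace.
#' @param params A [motion_model_params()].
#' @param master_seed Integer master seed.
#' @return List of [generate_trace()] results.
#' @export
generate_batch <- function(n_traces = 100, n_cps,
                           params = motion_model_params(), master_seed = 1) {
  stopifnot(n_traces >= 1)
  set.seed(master_seed)
  child <- sample.int(2147483646L, n_traces)
  lapply(seq_len(n_traces), function(i) {
    generate_trace(n_cps, params, seed = child[i],
                   trace_id = sprintf("trace-%04d", i))
  })
}

#' Tabulate a batch of traces
#' @param traces List of [generate_trace()] results.
#' @return Data frame with columns `trace_id`, `cp_index` (0-based), `dx`,
#'   `dy`, `dz` (mm).
#' @export
traces_to_df <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id,
               cp_index = seq_len(nrow(tr$displacements)) - 1L,
               dx = tr$displacements[, 1], dy = tr$displacements[, 2],
               dz = tr$displacements[, 3], row.names = NULL)
  }))
}
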