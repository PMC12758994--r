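#' Multileaf collimator models
#'
#' An `mlc_model` describes the leaf-pair geometry of a multileaf collimator
#' projected to the isocenter plane: the number of opposed leaf pairs, the
#' width of each pair along the axis orthogonal to leaf travel, and the
#' cumulative pair boundaries (`leaf_edges`) along that axis. All lengths are
#' millimetres in the isocenter plane, with the pair stack centred on the
#' beam axis.
#'
#' @param leaf_widths Numeric vector of per-pair widths (mm, isocenter plane).
#' @return An object of class `mlc_model` with fields `n_pairs`,
#'   `leaf_widths` and `leaf_edges` (length `n_pairs + 1`, strictly
#'   increasing, centred so the edges span `sum(leaf_widths)` about zero).
#' @export
mlc_model <- function(leaf_widths) {
  stopifnot(is.numeric(leaf_widths), length(leaf_widths) >= 1,
            all(leaf_widths > 0))
  span <- sum(leaf_widths)
  edges <- cumsum(c(-span / 2, leaf_widths))
  structure(
    list(n_pairs = length(leaf_widths),
         leaf_widths = as.numeric(leaf_widths),
         leaf_edges = edges),
    class = "mlc_model"
  )
}

#' High-definition 120-leaf MLC (HD120)
#'
#' The HD120 carries 60 opposed leaf pairs: the central 32 pairs project to
#' 2.5 mm width at isocenter and the peripheral 14 + 14 pairs to 5 mm, for a
#' total stack span of 220 mm.
#'
#' @return An `mlc_model` with 60 pairs.
#' @export
hd120_mlc <- function() {
  mlc_model(c(rep(5, 14), rep(2.5, 32), rep(5, 14)))
}

#' MLC aperture area of a control point
#'
#' Computes the open beam area defined by the MLC leaves, clipped by the jaw
#' window, as the sum of exact rectangle intersections in the isocenter
#' plane. A leaf pair contributes `(clipped pair width) x (clipped leaf
#' gap)`, where the pair width is clipped to the jaw y-window and the gap
#' `bank_b - bank_a` to the jaw x-window. Fully closed pairs and pairs fully
#' blocked by the jaws contribute zero. The area is invariant under
#' collimator rotation, so any stored collimator angle is ignored.
#'
#' @param cp A [control_point()].
#' @param mlc An [mlc_model()]; defaults to the HD120.
#' @return Aperture area in mm^2.
#' @export
aperture_area <- function(cp, mlc = hd120_mlc()) {
  stopifnot(inherits(cp, "control_point"), inherits(mlc, "mlc_model"))
  if (length(cp$bank_a) != mlc$n_pairs || length(cp$bank_b) != mlc$n_pairs) {
    stop("control point carries ", length(cp$bank_a),
         " leaf pairs but the MLC model has ", mlc$n_pairs, call. = FALSE)
  }
  j <- cp$jaws
  lo <- mlc$leaf_edges[-(mlc$n_pairs + 1)]
  hi <- mlc$leaf_edges[-1]
  wy <- pmax(0, pmin(hi, j[["y2"]]) - pmax(lo, j[["y1"]]))
  gx <- pmax(0, pmin(cp$bank_b, j[["x2"]]) - pmax(cp$bank_a, j[["x1"]]))
  sum(wy * gx)
}
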