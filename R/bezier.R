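# Quadratic Bezier densification of closed marked contours.
#
# The quadratic curve B(t) = (1-t)^2 M1 + 2(1-t)t C1 + t^2 M2 is the
# production smoother: it interpolates its endpoints exactly and stays
# inside the convex hull of {M1, C1, M2}, so it cannot overshoot the
# marked points. The cubic curve is implemented as a comparison utility
# and as the cross-check oracle for the affine-combination identity
# B_cubic(t) = (1-t) B_quad(M1,C1,C2; t) + t B_quad(C1,C2,M2; t).

#' Evaluate a quadratic Bezier curve
#'
#' @param M1,M2 numeric `(x, y)` endpoints (first and succeeding marked
#'   points).
#' @param C1 numeric `(x, y)` control point.
#' @param t evaluation parameter(s) in `[0, 1]`.
#' @return a `length(t)` x 2 matrix of curve points.
#' @export
eval_quad <- function(M1, C1, M2, t) {
  if (any(t < 0 | t > 1)) c3d_abort("domain_error", "t must lie in [0, 1]")
  u <- 1 - t
  cbind(u^2 * M1[1] + 2 * u * t * C1[1] + t^2 * M2[1],
        u^2 * M1[2] + 2 * u * t * C1[2] + t^2 * M2[2])
}

#' Evaluate a cubic Bezier curve
#'
#' Provided as a comparison utility (the pipeline smooths with the
#' quadratic curve); with deliberately wide control points it illustrates
#' the overshoot that motivates the quadratic choice.
#'
#' @param M1,M2 numeric `(x, y)` endpoints.
#' @param C1,C2 numeric `(x, y)` control points.
#' @param t evaluation parameter(s) in `[0, 1]`.
#' @return a `length(t)` x 2 matrix of curve points.
#' @export
eval_cubic <- function(M1, C1, C2, M2, t) {
  if (any(t < 0 | t > 1)) c3d_abort("domain_error", "t must lie in [0, 1]")
  u <- 1 - t
  cbind(u^3 * M1[1] + 3 * u^2 * t * C1[1] + 3 * u * t^2 * C2[1] + t^3 * M2[1],
        u^3 * M1[2] + 3 * u^2 * t * C1[2] + 3 * u * t^2 * C2[2] + t^3 * M2[2])
}

#' Smoothing configuration
#'
#' @param samples_per_segment points generated per marked-point edge
#'   (>= 1); 1 reproduces the input polygon. Default 8.
#' @param tangent_scale fraction of the edge length by which the control
#'   point follows the local tangent direction, in `(0, 1]`. Default 1/3.
#' @return a `smoothing_config` list.
#' @export
smoothing_config <- function(samples_per_segment = 8L, tangent_scale = 1 / 3) {
  samples_per_segment <- as.integer(samples_per_segment)
  if (samples_per_segment < 1L) c3d_abort("domain_error", "samples_per_segment must be >= 1")
  if (tangent_scale <= 0 || tangent_scale > 1) {
    c3d_abort("domain_error", "tangent_scale must be in (0, 1]")
  }
  structure(list(samples_per_segment = samples_per_segment,
                 tangent_scale = tangent_scale),
            class = "smoothing_config")
}

#' Derive quadratic control points for a closed polygon
#'
#' For each edge (M_i, M_{i+1}) of the cyclic polygon, the unit tangent
#' at M_i is the normalized direction of (M_{i+1} - M_{i-1}) (central
#' difference over the cyclic neighbors), and the control point is
#' `C1 = ((M_i + s d T_i) + (M_{i+1} - s d T_{i+1})) / 2` with
#' `d = |M_{i+1} - M_i|` and `s` the tangent scale. One segment per edge;
#' segment count equals point count.
#'
#' @param points n x 2 closed clockwise polygon (n >= 3).
#' @param config a [smoothing_config()].
#' @return list of quadratic segments, each `list(M1=, C1=, M2=)`.
#' @export
derive_controls <- function(points, config = smoothing_config()) {
  n <- nrow(points)
  if (n < 3L) c3d_abort("too_few_points", "need at least 3 points")
  s <- config$tangent_scale
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  tangents <- points[nxt, , drop = FALSE] - points[prv, , drop = FALSE]
  tlen <- sqrt(rowSums(tangents^2))
  if (any(tlen == 0)) c3d_abort("degenerate_edge", "coincident cyclic neighbors")
  tangents <- tangents / tlen
  lapply(seq_len(n), function(i) {
    j <- nxt[i]
    d <- sqrt(sum((points[j, ] - points[i, ])^2))
    if (d == 0) c3d_abort("degenerate_edge", "coincident consecutive points")
    C1 <- ((points[i, ] + s * d * tangents[i, ]) +
             (points[j, ] - s * d * tangents[j, ])) / 2
    list(M1 = points[i, ], C1 = C1, M2 = points[j, ])
  })
}

#' Densify a closed contour with quadratic Bezier curves
#'
#' Each edge of the marked polygon becomes a quadratic segment (control
#' points from [derive_controls()]) sampled uniformly in `t` at
#' `t = j / samples_per_segment`, `j = 0 ... samples_per_segment - 1`
#' (each segment's endpoint is the next segment's start, so no
#' duplicates). The output passes through every marked point bit-exactly
#' and preserves the input orientation.
#'
#' @param layer a closed `contour_layer`.
#' @param config a [smoothing_config()].
#' @return a closed `contour_layer` with
#'   `n_points * samples_per_segment` points.
#' @export
smooth_contour <- function(layer, config = smoothing_config()) {
  if (!layer$closed) c3d_abort("layer_open", "smooth_contour requires a closed layer")
  m <- config$samples_per_segment
  if (m == 1L) return(layer)
  segs <- derive_controls(layer$points, config)
  ts <- (seq_len(m) - 1L) / m
  out <- do.call(rbind, lapply(segs, function(sg) {
    p <- eval_quad(sg$M1, sg$C1, sg$M2, ts)
    p[1, ] <- sg$M1              # exact marked-point preservation
    p
  }))
  res <- layer
  res$extent <- NULL             # smoothed points may bow outside the raster
  res$points <- out
  res$closed <- TRUE
  res
}
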