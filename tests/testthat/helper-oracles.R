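# Independent reference implementations used as oracles. These stay
# deliberately naive (explicit loops, exhaustive enumeration) and share
# no code with the production paths they check.

# per-pixel display conversion: the definitional double loop
reference_display <- function(pixel, slope, intercept, wmin, wmax) {
  out <- matrix(0L, nrow(pixel), ncol(pixel))
  for (i in seq_len(nrow(pixel))) {
    for (j in seq_len(ncol(pixel))) {
      v <- pixel[i, j] * slope + intercept
      s <- floor(255 * (v - wmin) / (wmax - wmin) + 0.5)
      out[i, j] <- as.integer(min(255, max(0, s)))
    }
  }
  out
}

# exhaustive minimum of sum |secondary location - target| over all
# strictly increasing index subsequences of the given length
brute_force_decimation <- function(sec_locs, targets) {
  m <- length(targets)
  combos <- utils::combn(length(sec_locs), m)
  best <- NULL
  best_cost <- Inf
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    cost <- sum(abs(sec_locs[idx] - targets))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- idx
    }
  }
  best
}

# brute-force nearest edge of a closed polygon to a point
brute_force_nearest_edge <- function(pts, p) {
  n <- nrow(pts)
  d <- numeric(n)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(1, max(0, t))
    d[i] <- sqrt(sum((a + t * ab - p)^2))
  }
  which.min(d)
}

# exact orientation predicate: TRUE when q lies inside or on the
# triangle (a, b, c), using sign tests only
in_triangle <- function(q, a, b, c) {
  s <- function(p1, p2, p3) {
    (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  }
  d1 <- s(a, b, q); d2 <- s(b, c, q); d3 <- s(c, a, q)
  eps <- 1e-9 * max(1, abs(d1), abs(d2), abs(d3))
  !((d1 < -eps || d2 < -eps || d3 < -eps) && (d1 > eps || d2 > eps || d3 > eps))
}

make_polygon_layer <- function(points, kind = "lumen", z = 0, extent = NULL) {
  lay <- contour_layer(kind, z, extent = extent)
  for (i in seq_len(nrow(points))) lay <- add_point(lay, points[i, ])
  close_layer(lay)
}

# clockwise regular n-gon (image coordinates) about (cx, cy)
regular_ngon <- function(n, r, cx = 0, cy = 0) {
  th <- -2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ring_stack <- function(zs, n = 16, r = 10, cx = 20, cy = 20, kind = "lumen") {
  st <- contour_stack(kind)
  for (z in zs) st <- insert_layer(st, make_polygon_layer(regular_ngon(n, r, cx, cy), kind, z))
  st
}
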