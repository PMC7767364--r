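# Lumen/wall marking data model: closed per-slice polygons held in a
# doubly-linked ordered stack whose Z coordinate comes from the slice
# location. Marking lives purely in pixel {X, Y}; millimetres appear only
# in to_xyz(). Orientation is normalized to clockwise as seen on screen
# (image coordinates, y increasing downward), which corresponds to a
# negative shoelace signed area on the raw (x, y) values.

#' Create an empty contour layer
#'
#' @param kind `"lumen"` or `"wall"`.
#' @param slice_location the layer's Z position, mm.
#' @param extent optional `c(rows, cols)` of the host slice; when given,
#'   point coordinates are bounds-checked against the raster.
#' @return an open `contour_layer` with no points.
#' @export
contour_layer <- function(kind = c("lumen", "wall"), slice_location, extent = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(slice_location)) c3d_abort("domain_error", "slice_location must be finite")
  structure(list(points = matrix(numeric(0), ncol = 2),
                 kind = kind, slice_location = slice_location,
                 closed = FALSE, extent = extent,
                 prev = NA_integer_, next_ = NA_integer_),
            class = "contour_layer")
}

check_point <- function(layer, p) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p))) {
    c3d_abort("bounds_error", "a marked point must be a finite (x, y) pair")
  }
  if (!is.null(layer$extent)) {
    rows <- layer$extent[1]; cols <- layer$extent[2]
    if (p[1] < 0 || p[1] >= cols || p[2] < 0 || p[2] >= rows) {
      c3d_abort("bounds_error",
                sprintf("point (%g, %g) outside the %dx%d raster", p[1], p[2], rows, cols))
    }
  }
  p
}

#' Append a marked point to an open layer
#'
#' A point identical to the last one (within 1e-9 px) is silently ignored.
#'
#' @param layer an open `contour_layer`.
#' @param p numeric `(x, y)` in pixel coordinates (x = column, y = row,
#'   0-based, y increasing downward).
#' @return the layer with the point appended.
#' @export
add_point <- function(layer, p) {
  if (layer$closed) c3d_abort("layer_closed", "cannot add points to a closed layer")
  p <- check_point(layer, p)
  n <- nrow(layer$points)
  if (n > 0L && max(abs(layer$points[n, ] - p)) <= 1e-9) return(layer)
  layer$points <- rbind(layer$points, p, deparse.level = 0)
  layer
}

# shoelace signed area on raw (x, y) values; negative = clockwise on
# screen (y-down image coordinates)
signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Close a layer and normalize its orientation
#'
#' Requires at least 3 points; the last point implicitly connects to the
#' first. Point order is reversed when the shoelace test indicates the
#' polygon was entered counter-clockwise, so closed layers are always
#' clockwise in image coordinates. Closing an already-closed layer is a
#' no-op.
#'
#' @param layer a `contour_layer` with >= 3 points.
#' @return the closed layer.
#' @export
close_layer <- function(layer) {
  if (layer$closed) return(layer)
  n <- nrow(layer$points)
  if (n >= 2L && max(abs(layer$points[n, ] - layer$points[1, ])) <= 1e-9) {
    layer$points <- layer$points[-n, , drop = FALSE]   # drop explicit closure
    n <- n - 1L
  }
  if (n < 3L) c3d_abort("too_few_points", "a closed contour needs at least 3 points")
  a <- signed_area(layer$points)
  if (a == 0) c3d_abort("degenerate_edge", "contour has zero area")
  if (a > 0) layer$points <- layer$points[n:1, , drop = FALSE]
  layer$closed <- TRUE
  layer
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

#' Insert a point into a closed layer at the nearest edge
#'
#' The insertion position is chosen by brute-force minimum point-to-edge
#' distance over all edges of the closed polygon (including the closing
#' edge); the point is placed between that edge's endpoints.
#'
#' @param layer a closed `contour_layer`.
#' @param p the new `(x, y)` point.
#' @return the layer with the point inserted; orientation re-normalized.
#' @export
insert_point <- function(layer, p) {
  if (!layer$closed) c3d_abort("layer_open", "insert_point requires a closed layer")
  p <- check_point(layer, p)
  pts <- layer$points
  n <- nrow(pts)
  d <- vapply(seq_len(n), function(i) {
    point_segment_distance(p, pts[i, ], pts[if (i == n) 1L else i + 1L, ])
  }, 0)
  i <- which.min(d)
  layer$points <- rbind(pts[seq_len(i), , drop = FALSE], p,
                        if (i < n) pts[(i + 1L):n, , drop = FALSE], deparse.level = 0)
  renormalize(layer)
}

#' Move a point of a layer
#' @param layer a `contour_layer`.
#' @param i point index (1-based).
#' @param p the new `(x, y)` position.
#' @return the layer with the point moved; orientation re-normalized when
#'   closed.
#' @export
move_point <- function(layer, i, p) {
  n <- nrow(layer$points)
  if (i < 1L || i > n) c3d_abort("index_error", sprintf("point index %d out of range", i))
  layer$points[i, ] <- check_point(layer, p)
  if (layer$closed) renormalize(layer) else layer
}

#' Delete a point from a layer
#' @param layer a `contour_layer`.
#' @param i point index (1-based).
#' @return the layer without the point.
#' @export
delete_point <- function(layer, i) {
  n <- nrow(layer$points)
  if (i < 1L || i > n) c3d_abort("index_error", sprintf("point index %d out of range", i))
  if (layer$closed && n <= 3L) {
    c3d_abort("too_few_points", "deleting would leave fewer than 3 points in a closed layer")
  }
  layer$points <- layer$points[-i, , drop = FALSE]
  if (layer$closed) renormalize(layer) else layer
}

renormalize <- function(layer) {
  pts <- layer$points
  n <- nrow(pts)
  keep <- vapply(seq_len(n), function(i) {
    max(abs(pts[i, ] - pts[if (i == 1L) n else i - 1L, ])) > 1e-9
  }, TRUE)
  layer$points <- pts[keep, , drop = FALSE]
  layer$closed <- FALSE
  close_layer(layer)
}

#' Convert a closed layer to (x, y, z) millimetre coordinates
#'
#' @param layer a closed `contour_layer`.
#' @param pixel_spacing numeric `(row_mm, col_mm)`.
#' @return an n x 3 matrix: `x_mm = x * col_mm`, `y_mm = y * row_mm`,
#'   `z_mm = slice_location`; point order preserved.
#' @export
to_xyz <- function(layer, pixel_spacing) {
  if (!layer$closed) c3d_abort("layer_open", "to_xyz requires a closed layer")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    c3d_abort("domain_error", "pixel_spacing must be two positive values (row_mm, col_mm)")
  }
  cbind(x = layer$points[, 1] * pixel_spacing[2],
        y = layer$points[, 2] * pixel_spacing[1],
        z = layer$slice_location)
}

# ---- contour stacks -------------------------------------------------------

#' Create an empty contour stack
#' @param kind `"lumen"` or `"wall"`.
#' @return a `contour_stack` holding an ordered, doubly-linked list of
#'   layers (ascending slice location).
#' @export
contour_stack <- function(kind = c("lumen", "wall")) {
  kind <- match.arg(kind)
  structure(list(layers = list(), kind = kind), class = "contour_stack")
}

relink <- function(stack) {
  n <- length(stack$layers)
  for (i in seq_len(n)) {
    stack$layers[[i]]$prev <- if (i > 1L) i - 1L else NA_integer_
    stack$layers[[i]]$next_ <- if (i < n) i + 1L else NA_integer_
  }
  stack
}

#' Insert a closed layer into a stack
#'
#' Layers are kept sorted ascending by slice location with prev/next
#' links rebuilt; a layer at an existing slice location replaces the old
#' one.
#'
#' @param stack a `contour_stack`.
#' @param layer a closed `contour_layer` of the stack's kind.
#' @return the updated stack.
#' @export
insert_layer <- function(stack, layer) {
  if (!layer$closed) c3d_abort("layer_open", "only closed layers can enter a stack")
  if (layer$kind != stack$kind) {
    c3d_abort("domain_error", sprintf("cannot insert a %s layer into a %s stack",
                                      layer$kind, stack$kind))
  }
  locs <- stack_locations(stack)
  hit <- which(abs(locs - layer$slice_location) <= 1e-9)
  if (length(hit) == 1L) {
    stack$layers[[hit]] <- layer
  } else {
    stack$layers <- append(stack$layers, list(layer), after = sum(locs < layer$slice_location))
  }
  relink(stack)
}

#' Slice locations of a stack's layers
#' @param stack a `contour_stack`.
#' @return numeric vector, ascending.
#' @export
stack_locations <- function(stack) {
  vapply(stack$layers, `[[`, 0, "slice_location")
}

#' Validate a stack's link structure
#'
#' Checks that prev/next links are mutually consistent and that slice
#' locations strictly increase along next-links.
#'
#' @param stack a `contour_stack`.
#' @return `TRUE` invisibly; aborts on inconsistency.
#' @export
stack_validate <- function(stack) {
  n <- length(stack$layers)
  for (i in seq_len(n)) {
    lay <- stack$layers[[i]]
    nx <- lay$next_
    if (!is.na(nx)) {
      if (stack$layers[[nx]]$prev != i) {
        c3d_abort("format_error", "stack links are inconsistent (next.prev != self)")
      }
      if (stack$layers[[nx]]$slice_location <= lay$slice_location) {
        c3d_abort("format_error", "slice locations are not strictly increasing along next-links")
      }
    } else if (i != n) {
      c3d_abort("format_error", "non-terminal layer with no next link")
    }
    if (is.na(lay$prev) && i != 1L) {
      c3d_abort("format_error", "non-initial layer with no prev link")
    }
  }
  invisible(TRUE)
}

#' Ray-casting point-in-polygon test
#' @param p `(x, y)` point.
#' @param polygon n x 2 closed polygon (implicit last-to-first edge).
#' @return `TRUE` when `p` is strictly inside.
#' @export
point_in_polygon <- function(p, polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- nrow(polygon)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > p[2]) != (y[j] > p[2])) {
      xint <- x[i] + (p[2] - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Bundle lumen and wall stacks into a contour set
#'
#' Enforces the anatomical invariant that on any slice carrying both
#' contours the wall polygon encloses every lumen vertex.
#'
#' @param lumen,wall `contour_stack`s of the respective kinds.
#' @param source_label sequence label the marking was made on.
#' @return a `contour_set`.
#' @export
contour_set <- function(lumen, wall, source_label) {
  stopifnot(inherits(lumen, "contour_stack"), inherits(wall, "contour_stack"))
  if (lumen$kind != "lumen" || wall$kind != "wall") {
    c3d_abort("domain_error", "contour_set needs a lumen stack and a wall stack")
  }
  wall_locs <- stack_locations(wall)
  for (lay in lumen$layers) {
    hit <- which(abs(wall_locs - lay$slice_location) <= 1e-9)
    if (length(hit) == 1L) {
      wp <- wall$layers[[hit]]$points
      ok <- all(apply(lay$points, 1L, point_in_polygon, polygon = wp))
      if (!ok) {
        c3d_abort("domain_error",
                  sprintf("wall does not enclose lumen at slice location %g", lay$slice_location))
      }
    }
  }
  structure(list(lumen = lumen, wall = wall, source_label = source_label),
            class = "contour_set")
}

#' Reproduce primary markings onto the secondary series
#'
#' Copies every marked polygon verbatim (pixel coordinates unchanged) to
#' each secondary sequence, attaching it to the slice that corresponds to
#' the marked primary slice in the registration table. A warning is
#' emitted when pixel spacings differ between the primary and a
#' secondary, since coordinates are not resampled.
#'
#' @param contours a `contour_set` marked on the registered primary.
#' @param registered a `registered_study` (see [rationalize()]).
#' @return named list: sequence label -> `contour_set`.
#' @export
propagate <- function(contours, registered) {
  if (!identical(contours$source_label, registered$primary_label)) {
    c3d_abort("domain_error",
              sprintf("contours were marked on %s but the registered primary is %s",
                      contours$source_label, registered$primary_label))
  }
  prim_locs <- registered$locations
  prim_spacing <- registered$series[[registered$primary_label]]$slices[[1]]$pixel_spacing
  out <- list()
  for (label in setdiff(names(registered$series), registered$primary_label)) {
    sec <- registered$series[[label]]
    if (max(abs(sec$slices[[1]]$pixel_spacing - prim_spacing)) > 1e-9) {
      c3d_warn("spacing_mismatch",
               sprintf("pixel spacing of %s differs from the primary; markings copied without resampling", label))
    }
    lum <- contour_stack("lumen"); wal <- contour_stack("wall")
    for (kind in c("lumen", "wall")) {
      for (lay in contours[[kind]]$layers) {
        k <- which(abs(prim_locs - lay$slice_location) <= 1e-6)
        if (length(k) != 1L) {
          c3d_abort("unregistered_slice",
                    sprintf("marked slice location %g is not in the registration table",
                            lay$slice_location))
        }
        copy <- lay
        copy$slice_location <- sec$locations[k]
        if (kind == "lumen") lum <- insert_layer(lum, copy) else wal <- insert_layer(wal, copy)
      }
    }
    out[[label]] <- contour_set(lum, wal, label)
  }
  out
}

# ---- JSON sidecar ---------------------------------------------------------

stack_to_list <- function(stack) {
  lapply(stack$layers, function(lay) {
    list(slice_location = lay$slice_location,
         points = unname(lapply(seq_len(nrow(lay$points)),
                                function(i) as.numeric(lay$points[i, ]))))
  })
}

#' Save a contour set as a JSON sidecar
#'
#' Schema: `{source_label, lumen: [{slice_location, points: [[x,y],...]}],
#' wall: [...]}`; coordinates at full precision. The same file format is
#' both the marking input and the propagation output of the command-line
#' tools.
#'
#' @param set a `contour_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_contours <- function(set, path) {
  doc <- list(source_label = set$source_label,
              lumen = stack_to_list(set$lumen),
              wall = stack_to_list(set$wall))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

list_to_stack <- function(entries, kind) {
  stack <- contour_stack(kind)
  for (e in entries) {
    if (is.null(e$slice_location) || is.null(e$points) || length(e$points) < 3L) {
      c3d_abort("format_error", "contour entry missing slice_location or has < 3 points")
    }
    lay <- contour_layer(kind, as.numeric(e$slice_location))
    for (p in e$points) lay <- add_point(lay, as.numeric(p))
    stack <- insert_layer(stack, close_layer(lay))
  }
  stack
}

#' Load a contour set from a JSON sidecar
#'
#' @param path path to a file written by [save_contours()] (or produced
#'   by hand in the documented schema). Layer order is reconstructed from
#'   sorted slice locations; orientation is re-normalized.
#' @return a `contour_set`.
#' @export
load_contours <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(doc) || is.null(doc$source_label) || is.null(doc$lumen) || is.null(doc$wall)) {
    c3d_abort("format_error", sprintf("not a valid contour sidecar: %s", path))
  }
  contour_set(list_to_stack(doc$lumen, "lumen"),
              list_to_stack(doc$wall, "wall"),
              doc$source_label)
}
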