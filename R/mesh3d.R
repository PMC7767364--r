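# Surface lofting from parallel planar contours.
#
# Each closed contour is resampled to a fixed number of ring points by
# cumulative arc length with a deterministic start (the vertex furthest
# in +x from the centroid), which establishes vertex correspondence
# between adjacent layers; corresponding points are stitched with two
# triangles per quad. Meshes carry per-vertex normals (area-weighted,
# outward) and cylindrical texture coordinates, and can be exported as
# Wavefront OBJ or binary STL.

#' Loft configuration
#'
#' @param ring_samples ring points per layer (N >= 8). Default 64.
#' @param cap_ends close the tube with triangle fans about the end-ring
#'   centroids (required for volume). Default `FALSE`, matching an open
#'   vessel segment.
#' @param mm_scale `(row_mm, col_mm)` pixel spacing used to convert pixel
#'   contours to millimetres.
#' @return a `loft_config` list.
#' @export
loft_config <- function(ring_samples = 64L, cap_ends = FALSE, mm_scale = c(0.5, 0.5)) {
  ring_samples <- as.integer(ring_samples)
  if (ring_samples < 8L) c3d_abort("domain_error", "ring_samples must be >= 8")
  structure(list(ring_samples = ring_samples, cap_ends = cap_ends, mm_scale = mm_scale),
            class = "loft_config")
}

#' Resample a closed polygon to N points uniform in arc length
#'
#' The start point is the input vertex with the largest x relative to the
#' polygon centroid (ties: smallest y); the remaining points are placed
#' at equal arc-length steps of perimeter/N along the boundary.
#' Orientation is preserved.
#'
#' @param polygon n x 2 (or n x 3, constant z) closed polygon, n >= 3.
#' @param N number of output points, >= 8.
#' @return an N x `ncol(polygon)` matrix of ring points.
#' @export
resample_ring <- function(polygon, N) {
  if (nrow(polygon) < 3L) c3d_abort("too_few_points", "polygon needs >= 3 points")
  if (N < 8L) c3d_abort("domain_error", "N must be >= 8")
  ctr <- colMeans(polygon)
  relx <- polygon[, 1] - ctr[1]
  start <- which(relx == max(relx))
  if (length(start) > 1L) start <- start[which.min(polygon[start, 2])]
  idx <- c(start:nrow(polygon), if (start > 1L) 1:(start - 1L))
  pts <- polygon[idx, , drop = FALSE]
  pts <- rbind(pts, pts[1, ])                    # explicit closure
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  if (per == 0) c3d_abort("degenerate_edge", "polygon has zero perimeter")
  targets <- per * (seq_len(N) - 1L) / N
  out <- matrix(0, N, ncol(polygon))
  j <- 1L
  for (k in seq_len(N)) {
    while (cum[j + 1L] < targets[k] && j < length(seg)) j <- j + 1L
    f <- if (seg[j] == 0) 0 else (targets[k] - cum[j]) / seg[j]
    out[k, ] <- pts[j, ] + f * (pts[j + 1L, ] - pts[j, ])
  }
  out
}

#' Loft a smoothed contour stack into a triangle mesh
#'
#' Each layer is converted to millimetres via [to_xyz()] and resampled to
#' `ring_samples` points; adjacent rings are stitched quad-by-quad, each
#' quad split along the (layer, i) -> (layer+1, i+1) diagonal. Texture
#' coordinates are cylindrical (`u` around the ring, `v` along the
#' stack); per-vertex normals are area-weighted averages of incident face
#' normals, oriented outward. Faces are wound counter-clockwise seen from
#' outside.
#'
#' @param stack a `contour_stack` of >= 2 closed layers with strictly
#'   increasing slice locations.
#' @param config a [loft_config()].
#' @return a `triangle_mesh`: `vertices` (V x 3, mm), `faces` (F x 3,
#'   1-based), `normals` (V x 3, unit), `uvs` (V x 2), `capped`.
#' @export
loft <- function(stack, config = loft_config()) {
  L <- length(stack$layers)
  if (L < 2L) c3d_abort("too_few_layers", "lofting needs at least 2 marked layers")
  locs <- stack_locations(stack)
  if (any(diff(locs) <= 0)) c3d_abort("non_monotone_z", "slice locations must strictly increase")
  N <- config$ring_samples

  rings <- lapply(stack$layers, function(lay) {
    xyz <- to_xyz(lay, config$mm_scale)
    resample_ring(xyz, N)
  })
  vertices <- do.call(rbind, rings)
  uvs <- cbind(rep((seq_len(N) - 1L) / N, times = L),
               rep((seq_len(L) - 1L) / (L - 1L), each = N))

  vid <- function(l, i) (l - 1L) * N + ((i - 1L) %% N) + 1L
  faces <- matrix(0L, 0L, 3L)
  for (l in seq_len(L - 1L)) {
    i <- seq_len(N)
    a <- vid(l, i); b <- vid(l, i + 1L); c <- vid(l + 1L, i + 1L); d <- vid(l + 1L, i)
    faces <- rbind(faces, cbind(a, b, c), cbind(a, c, d))
  }

  # orient the tube outward: test one side face against the ring centroid
  ctr1 <- colMeans(rings[[1]])
  f <- faces[1, ]
  nrm <- cross3(vertices[f[2], ] - vertices[f[1], ], vertices[f[3], ] - vertices[f[1], ])
  fc <- colMeans(vertices[f, ])
  radial <- fc - ctr1
  radial[3] <- 0
  if (sum(nrm * radial) < 0) faces <- faces[, c(1L, 3L, 2L)]

  if (isTRUE(config$cap_ends)) {
    c_bot <- colMeans(rings[[1]]); c_top <- colMeans(rings[[L]])
    vertices <- rbind(vertices, c_bot, c_top)
    uvs <- rbind(uvs, c(0.5, 0), c(0.5, 1))
    ib <- nrow(vertices) - 1L; it <- nrow(vertices)
    i <- seq_len(N)
    bot <- cbind(rep(ib, N), vid(1L, i + 1L), vid(1L, i))
    top <- cbind(rep(it, N), vid(L, i), vid(L, i + 1L))
    # match the side winding so shared edges are traversed oppositely
    if (!edge_opposed(faces, bot)) bot <- bot[, c(1L, 3L, 2L)]
    if (!edge_opposed(faces, top)) top <- top[, c(1L, 3L, 2L)]
    faces <- rbind(faces, bot, top)
  }

  normals <- vertex_normals(vertices, faces)
  # outward check: flip everything if normals point toward the axis
  axis_pts <- ring_axis_points(vertices, L, N)
  outward <- mean(rowSums(normals[seq_len(L * N), ] * (vertices[seq_len(L * N), ] - axis_pts)))
  if (outward < 0) {
    faces <- faces[, c(1L, 3L, 2L)]
    normals <- -normals
  }

  structure(list(vertices = unname(vertices), faces = unname(faces),
                 normals = normals, uvs = unname(uvs),
                 capped = isTRUE(config$cap_ends),
                 layers = L, ring_samples = N),
            class = "triangle_mesh")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

ring_axis_points <- function(vertices, L, N) {
  do.call(rbind, lapply(seq_len(L), function(l) {
    ctr <- colMeans(vertices[((l - 1L) * N + 1L):(l * N), , drop = FALSE])
    matrix(ctr, N, 3L, byrow = TRUE)
  }))
}

# TRUE when every edge of `new_faces` already present in `faces` is
# traversed in the opposite direction there (consistent winding)
edge_opposed <- function(faces, new_faces) {
  dir_edges <- function(ff) {
    rbind(ff[, c(1, 2)], ff[, c(2, 3)], ff[, c(3, 1)])
  }
  old <- dir_edges(faces)
  new <- dir_edges(new_faces)
  old_keys <- paste(old[, 1], old[, 2])
  new_rev <- paste(new[, 2], new[, 1])
  new_fwd <- paste(new[, 1], new[, 2])
  shared_ok <- sum(new_rev %in% old_keys)
  shared_bad <- sum(new_fwd %in% old_keys)
  shared_ok >= shared_bad
}

vertex_normals <- function(vertices, faces) {
  normals <- matrix(0, nrow(vertices), 3L)
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    n <- cross3(vertices[f[2], ] - vertices[f[1], ], vertices[f[3], ] - vertices[f[1], ])
    normals[f[1], ] <- normals[f[1], ] + n   # |n| = 2*area: area weighting
    normals[f[2], ] <- normals[f[2], ] + n
    normals[f[3], ] <- normals[f[3], ] + n
  }
  len <- sqrt(rowSums(normals^2))
  len[len == 0] <- 1
  normals / len
}

#' Audit mesh combinatorics and winding
#'
#' @param mesh a `triangle_mesh`.
#' @return list: `V`, `E`, `F`, `euler` (V - E + F), `boundary_edges`
#'   (edges on exactly 1 face), `nonmanifold_edges` (edges on > 2 faces),
#'   `winding_consistent` (every interior edge traversed once in each
#'   direction).
#' @export
mesh_audit <- function(mesh) {
  f <- mesh$faces
  dir_edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                pmax(dir_edges[, 1], dir_edges[, 2]))
  tab <- table(keys)
  dkeys <- paste(dir_edges[, 1], dir_edges[, 2])
  dtab <- table(dkeys)
  list(V = nrow(mesh$vertices),
       E = length(tab),
       F = nrow(f),
       euler = nrow(mesh$vertices) - length(tab) + nrow(f),
       boundary_edges = sum(tab == 1L),
       nonmanifold_edges = sum(tab > 2L),
       winding_consistent = all(dtab == 1L))
}

#' Signed mesh volume by the divergence theorem
#'
#' Sums signed tetrahedron volumes `det(v1, v2, v3) / 6` over all faces;
#' positive for a closed mesh with outward (counter-clockwise) winding,
#' negative when the winding is flipped.
#'
#' @param mesh a closed (capped) `triangle_mesh`.
#' @return volume in cubic millimetres (signed).
#' @export
mesh_volume <- function(mesh) {
  audit <- mesh_audit(mesh)
  if (audit$boundary_edges > 0L) {
    c3d_abort("open_mesh", sprintf("volume undefined: mesh has %d boundary edges",
                                   audit$boundary_edges))
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Total surface area of a mesh
#' @param mesh a `triangle_mesh`.
#' @return area in square millimetres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  total <- 0
  for (k in seq_len(nrow(f))) {
    n <- cross3(v[f[k, 2], ] - v[f[k, 1], ], v[f[k, 3], ] - v[f[k, 1], ])
    total <- total + sqrt(sum(n^2)) / 2
  }
  total
}

# ---- export / import ------------------------------------------------------

#' Export a mesh to Wavefront OBJ or binary STL
#'
#' OBJ writes `v`/`vt`/`vn` and `f v/vt/vn` lines with 1-based indices at
#' full decimal precision (lossless round trip). STL is the standard
#' little-endian binary layout (80-byte header, float32 facets), so
#' coordinates round-trip to 32-bit float precision.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"obj"` or `"stl"` (case-insensitive).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = c("obj", "stl")) {
  format <- tolower(format[1])
  if (!format %in% c("obj", "stl")) {
    c3d_abort("unsupported_format", sprintf("unsupported mesh format: %s", format))
  }
  if (format == "obj") {
    v <- mesh$vertices; n <- mesh$normals; uv <- mesh$uvs; f <- mesh$faces
    lines <- c(
      sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
      sprintf("vt %.17g %.17g", uv[, 1], uv[, 2]),
      sprintf("vn %.17g %.17g %.17g", n[, 1], n[, 2], n[, 3]),
      sprintf("f %d/%d/%d %d/%d/%d %d/%d/%d",
              f[, 1], f[, 1], f[, 1], f[, 2], f[, 2], f[, 2], f[, 3], f[, 3], f[, 3])
    )
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
    v <- mesh$vertices
    for (k in seq_len(nrow(mesh$faces))) {
      f <- mesh$faces[k, ]
      fn <- cross3(v[f[2], ] - v[f[1], ], v[f[3], ] - v[f[1], ])
      len <- sqrt(sum(fn^2)); if (len > 0) fn <- fn / len
      writeBin(as.numeric(c(fn, t(v[f, ]))), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' Import a mesh written by [export_mesh()]
#'
#' @param path mesh file path.
#' @param format `"obj"` or `"stl"`.
#' @return a `triangle_mesh` (STL meshes have vertices merged by exact
#'   float32 coordinate equality and carry no uvs).
#' @export
import_mesh <- function(path, format = c("obj", "stl")) {
  format <- tolower(format[1])
  if (format == "obj") {
    lines <- readLines(path)
    get_num <- function(prefix, n) {
      sel <- lines[startsWith(lines, prefix)]
      if (length(sel) == 0L) return(matrix(numeric(0), ncol = n))
      do.call(rbind, lapply(strsplit(sel, " +"), function(x) as.numeric(x[-1])))
    }
    v <- get_num("v ", 3)
    vt <- get_num("vt ", 2)
    vn <- get_num("vn ", 3)
    fl <- lines[startsWith(lines, "f ")]
    f <- do.call(rbind, lapply(strsplit(fl, " +"), function(x) {
      as.integer(vapply(strsplit(x[-1], "/"), `[[`, "", 1L))
    }))
    structure(list(vertices = v, faces = f, normals = vn, uvs = vt,
                   capped = NA), class = "triangle_mesh")
  } else if (format == "stl") {
    buf <- readBin(path, "raw", n = file.info(path)$size)
    nfaces <- readBin(buf[81:84], "integer", size = 4L, endian = "little")
    verts <- matrix(0, 3L * nfaces, 3L)
    pos <- 85L
    for (k in seq_len(nfaces)) {
      vals <- readBin(buf[pos:(pos + 47L)], "numeric", n = 12L, size = 4L, endian = "little")
      verts[(3L * k - 2L):(3L * k), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
      pos <- pos + 50L
    }
    key <- apply(verts, 1L, paste, collapse = ",")
    uniq <- !duplicated(key)
    vid <- match(key, key[uniq])
    v <- verts[uniq, , drop = FALSE]
    f <- matrix(vid, ncol = 3L, byrow = TRUE)
    structure(list(vertices = v, faces = f,
                   normals = vertex_normals(v, f), uvs = NULL,
                   capped = NA), class = "triangle_mesh")
  } else {
    c3d_abort("unsupported_format", sprintf("unsupported mesh format: %s", format))
  }
}
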