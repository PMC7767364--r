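# Synthetic five-sequence DICOM phantom: a straight (or user-defined)
# tubular vessel with known lumen and wall radii, rendered into the two
# gap regimes typical of carotid protocols — thick-gap spin-echo stacks
# (T1, post-contrast T1, T2) and thin-gap 3D acquisitions (TOF,
# MP-RAGE). Ground-truth contours accompany the images so the whole
# pipeline can be validated geometrically without patient data.

#' Phantom specification
#'
#' @param lumen_radius_fn function z (mm) -> lumen radius (mm). Default
#'   constant 3.
#' @param wall_radius_fn function z -> outer wall radius (mm). Default
#'   constant 5; must exceed the lumen radius everywhere.
#' @param center_fn function z -> `(x_mm, y_mm)` vessel center. Default
#'   fixed at the image center.
#' @param image_size `(rows, cols)`. Default `(128, 128)`.
#' @param pixel_spacing `(row_mm, col_mm)`. Default `(0.5, 0.5)`.
#' @param sequences data frame with columns `label`, `description`,
#'   `gap`, `count`, `start`; defaults to the canonical protocol:
#'   T1/T1CE/T2 at gap 2.0 mm x 20 slices and MPRAGE/TOF at gap 0.5 mm x
#'   80 slices, all starting at 0 mm.
#' @param noise_sd additive Gaussian intensity noise (stored units).
#'   Default 20.
#' @param seed RNG seed controlling the noise. Default 42.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(lumen_radius_fn = function(z) 3.0,
                         wall_radius_fn = function(z) 5.0,
                         center_fn = NULL,
                         image_size = c(128L, 128L),
                         pixel_spacing = c(0.5, 0.5),
                         sequences = default_phantom_sequences(),
                         noise_sd = 20,
                         seed = 42L) {
  if (is.null(center_fn)) {
    cx <- floor(image_size[2] / 2) * pixel_spacing[2]
    cy <- floor(image_size[1] / 2) * pixel_spacing[1]
    center_fn <- function(z) c(cx, cy)
  }
  spec <- structure(list(
    lumen_radius_fn = lumen_radius_fn, wall_radius_fn = wall_radius_fn,
    center_fn = center_fn, image_size = as.integer(image_size),
    pixel_spacing = pixel_spacing, sequences = sequences,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
  for (z in phantom_z_range(spec)) {
    if (!(wall_radius_fn(z) > lumen_radius_fn(z) && lumen_radius_fn(z) > 0)) {
      c3d_abort("domain_error",
                sprintf("need wall_radius(z) > lumen_radius(z) > 0 at z = %g", z))
    }
  }
  spec
}

#' Default phantom sequence protocol
#' @return data frame of the five sequences with the paperless canonical
#'   two-gap-regime geometry: three thick-gap stacks (2.0 mm x 20) and
#'   two thin-gap stacks (0.5 mm x 80).
#' @export
default_phantom_sequences <- function() {
  data.frame(
    label = c("T1", "T1CE", "T2", "MPRAGE", "TOF"),
    description = c("T1 FS TSE BB", "T1 FS TSE BB CM", "T2 FS TSE BB",
                    "3D MP-RAGE_UW_d8000", "3D TOF Neck"),
    gap = c(2.0, 2.0, 2.0, 0.5, 0.5),
    count = c(20L, 20L, 20L, 80L, 80L),
    start = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

phantom_z_range <- function(spec) {
  zs <- unlist(lapply(seq_len(nrow(spec$sequences)), function(i) {
    s <- spec$sequences[i, ]
    s$start + s$gap * (seq_len(s$count) - 1L)
  }))
  range(zs)
}

# deterministic per-slice RNG stream, independent of the caller's RNG
with_slice_rng <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed * 1000L + stream) %% .Machine$integer.max)
  force(expr)
}

#' Render one phantom slice
#'
#' Noiseless tissue intensities: background 100, lumen disk 400, wall
#' annulus 900; additive Gaussian noise of sd `noise_sd` clipped to
#' `[0, 4095]`. Deterministic given the spec seed and the stream index.
#'
#' @param spec a `phantom_spec`.
#' @param z slice position, mm.
#' @param stream integer distinguishing the noise stream of this slice
#'   (unique per sequence/slice in [generate_study()]).
#' @return integer matrix (rows x cols) of stored 16-bit values.
#' @export
render_slice <- function(spec, z, stream = 0L) {
  rows <- spec$image_size[1]; cols <- spec$image_size[2]
  ctr <- spec$center_fn(z)
  x_mm <- (seq_len(cols) - 1L) * spec$pixel_spacing[2]
  y_mm <- (seq_len(rows) - 1L) * spec$pixel_spacing[1]
  dx2 <- outer(rep(1, rows), (x_mm - ctr[1])^2)
  dy2 <- outer((y_mm - ctr[2])^2, rep(1, cols))
  r <- sqrt(dx2 + dy2)
  img <- matrix(100, rows, cols)
  img[r <= spec$wall_radius_fn(z)] <- 900
  img[r <= spec$lumen_radius_fn(z)] <- 400
  if (spec$noise_sd > 0) {
    noise <- with_slice_rng(spec$seed, stream,
                            matrix(stats::rnorm(rows * cols, 0, spec$noise_sd), rows, cols))
    img <- img + noise
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 4095] <- 4095
  storage.mode(img) <- "integer"
  img
}

#' Ground-truth lumen and wall polygons at one slice
#'
#' Regular n-gons on the true circles, converted to pixel coordinates and
#' oriented clockwise in image coordinates.
#'
#' @param spec a `phantom_spec`.
#' @param z slice position, mm (must lie within the generated range).
#' @param n_points vertices per polygon (default 32).
#' @return list with closed `contour_layer`s `lumen` and `wall`.
#' @export
truth_contours <- function(spec, z, n_points = 32L) {
  if (n_points < 3L) c3d_abort("too_few_points", "n_points must be >= 3")
  zr <- phantom_z_range(spec)
  if (z < zr[1] - 1e-9 || z > zr[2] + 1e-9) {
    c3d_abort("domain_error", sprintf("z = %g outside the generated range [%g, %g]",
                                      z, zr[1], zr[2]))
  }
  ctr <- spec$center_fn(z)
  make <- function(kind, radius_mm) {
    # clockwise in image coordinates (y down): decreasing mathematical angle
    theta <- -2 * pi * (seq_len(n_points) - 1L) / n_points
    x_px <- (ctr[1] + radius_mm * cos(theta)) / spec$pixel_spacing[2]
    y_px <- (ctr[2] + radius_mm * sin(theta)) / spec$pixel_spacing[1]
    lay <- contour_layer(kind, z, extent = spec$image_size)
    for (i in seq_len(n_points)) lay <- add_point(lay, c(x_px[i], y_px[i]))
    close_layer(lay)
  }
  list(lumen = make("lumen", spec$lumen_radius_fn(z)),
       wall = make("wall", spec$wall_radius_fn(z)))
}

#' Generate a synthetic five-sequence DICOM study
#'
#' Writes one sub-directory per sequence (files shuffled on disk relative
#' to slice order, so loading must sort by Slice Location), plus
#' `truth_contours.json` (ground-truth lumen/wall polygons on the
#' thick-gap grid, marked on T1) and `truth_geometry.json` (tabulated
#' radius functions). The output is loadable by [scan_study_dir()] /
#' [load_series()] without warnings.
#'
#' @param spec a `phantom_spec`.
#' @param out_dir output directory (created if absent).
#' @param truth_points vertices per ground-truth polygon (default 32).
#' @return the `study_layout` of the generated study, invisibly.
#' @export
generate_study <- function(spec, out_dir, truth_points = 32L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stream <- 0L
  for (i in seq_len(nrow(spec$sequences))) {
    s <- spec$sequences[i, ]
    sdir <- file.path(out_dir, sprintf("series_%02d", i))
    dir.create(sdir, showWarnings = FALSE)
    zs <- s$start + s$gap * (seq_len(s$count) - 1L)
    # shuffle on-disk file numbering so ordering must come from the tag
    file_order <- rev(seq_along(zs))
    for (k in seq_along(zs)) {
      stream <- stream + 1L
      img <- render_slice(spec, zs[k], stream)
      write_dicom(file.path(sdir, sprintf("IM%04d.dcm", file_order[k])),
                  img, slice_location = zs[k],
                  pixel_spacing = spec$pixel_spacing,
                  series_description = s$description,
                  instance_number = k)
    }
  }

  t1 <- spec$sequences[spec$sequences$label == "T1", ]
  truth_zs <- if (nrow(t1) == 1L) {
    t1$start + t1$gap * (seq_len(t1$count) - 1L)
  } else {
    s <- spec$sequences[1, ]
    s$start + s$gap * (seq_len(s$count) - 1L)
  }
  lum <- contour_stack("lumen"); wal <- contour_stack("wall")
  for (z in truth_zs) {
    tc <- truth_contours(spec, z, truth_points)
    lum <- insert_layer(lum, tc$lumen)
    wal <- insert_layer(wal, tc$wall)
  }
  truth <- contour_set(lum, wal, "T1")
  save_contours(truth, file.path(out_dir, "truth_contours.json"))
  jsonlite::write_json(
    list(z = truth_zs,
         lumen_radius_mm = vapply(truth_zs, spec$lumen_radius_fn, 0),
         wall_radius_mm = vapply(truth_zs, spec$wall_radius_fn, 0),
         center_mm = lapply(truth_zs, spec$center_fn),
         pixel_spacing = spec$pixel_spacing,
         image_size = spec$image_size),
    file.path(out_dir, "truth_geometry.json"), digits = NA)
  invisible(scan_study_dir(out_dir))
}
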