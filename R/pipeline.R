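# End-to-end pipeline: validate -> register -> propagate -> smooth ->
# loft -> export, with a machine-readable JSON report. Fully
# deterministic: rerunning on the same inputs produces byte-identical
# meshes and reports.

#' Pipeline configuration
#'
#' @param gap_threshold registration gap threshold, mm (see
#'   [registration_config()]).
#' @param samples_per_segment Bezier densification per edge (see
#'   [smoothing_config()]).
#' @param ring_samples ring points per lofted layer (see [loft_config()]).
#' @param cap_ends close tube ends (enables volume reporting).
#' @param formats mesh output formats, subset of `c("obj", "stl")`.
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic; the seed matters only when generating phantoms).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gap_threshold = 1.8, samples_per_segment = 8L,
                            ring_samples = 64L, cap_ends = FALSE,
                            formats = "obj", seed = 42L) {
  structure(list(gap_threshold = gap_threshold,
                 samples_per_segment = as.integer(samples_per_segment),
                 ring_samples = as.integer(ring_samples),
                 cap_ends = cap_ends, formats = formats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Densify every layer of a contour stack
#' @param stack a `contour_stack` of closed layers.
#' @param config a [pipeline_config()] (only `samples_per_segment` is
#'   used).
#' @return the stack with each layer replaced by its Bezier-densified
#'   version.
#' @export
smooth_stack <- function(stack, config) {
  sm <- smoothing_config(samples_per_segment = config$samples_per_segment)
  out <- contour_stack(stack$kind)
  for (lay in stack$layers) out <- insert_layer(out, smooth_contour(lay, sm))
  out
}

#' Run the full reconstruction pipeline
#'
#' Validates the study layout, loads the five series, registers them with
#' the contour file's source sequence as primary (initial slices
#' auto-assigned by nearest slice location), propagates the markings to
#' the secondary sets, densifies the lumen and wall stacks with quadratic
#' Bezier curves, lofts them into triangle meshes, and exports the
#' meshes.
#'
#' @param study_dir study directory with the five sequence
#'   sub-directories.
#' @param contours_file JSON contour sidecar (see [save_contours()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory for meshes and `report.json`.
#' @param dry_run when `TRUE`, compute and return the report but write no
#'   files.
#' @return the report, invisibly: per-series counts/gaps, registration
#'   summary, contour layer counts, per-mesh vertex/face counts
#'   (and volumes when capped), output paths.
#' @export
run_pipeline <- function(study_dir, contours_file, config = pipeline_config(),
                         out_dir = file.path(study_dir, "output"),
                         dry_run = FALSE) {
  study <- load_study(study_dir)
  contours <- load_contours(contours_file)
  study <- select_primary(study, contours$source_label)
  study <- auto_assign_initial(study)
  registered <- rationalize(study, registration_config(gap_threshold = config$gap_threshold))
  propagated <- propagate(contours, registered)

  spacing <- registered$series[[registered$primary_label]]$slices[[1]]$pixel_spacing
  lcfg <- loft_config(ring_samples = config$ring_samples,
                      cap_ends = config$cap_ends, mm_scale = spacing)

  meshes <- list()
  mesh_report <- list()
  for (kind in c("lumen", "wall")) {
    sm <- smooth_stack(contours[[kind]], config)
    mesh <- loft(sm, lcfg)
    meshes[[kind]] <- mesh
    entry <- list(vertices = nrow(mesh$vertices), faces = nrow(mesh$faces),
                  layers = mesh$layers, ring_samples = mesh$ring_samples)
    if (config$cap_ends) entry$volume_mm3 <- mesh_volume(mesh)
    mesh_report[[kind]] <- entry
  }

  series_report <- lapply(names(registered$series), function(label) {
    s <- study$series[[label]]
    list(label = label, loaded_count = series_length(s), loaded_gap = s$gap,
         retained_count = series_length(registered$series[[label]]),
         retained_gap = registered$series[[label]]$gap,
         offset_mm = if (label == registered$primary_label) 0 else
           unname(registered$offsets[[label]]))
  })
  names(series_report) <- names(registered$series)

  report <- list(
    study_dir = study_dir,
    primary_label = registered$primary_label,
    gap_mm = registered$gap,
    registered_count = length(registered$locations),
    series = series_report,
    contour_layers = list(lumen = length(contours$lumen$layers),
                          wall = length(contours$wall$layers)),
    propagated_to = names(propagated),
    meshes = mesh_report,
    config = unclass(config)
  )
  if (config$cap_ends) {
    report$volumes <- list(lumen = mesh_report$lumen$volume_mm3,
                           wall = mesh_report$wall$volume_mm3)
  }

  if (!dry_run) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)
    for (kind in c("lumen", "wall")) {
      for (fmt in config$formats) {
        p <- file.path(out_dir, paste0(kind, ".", fmt))
        export_mesh(meshes[[kind]], p, fmt)
        outputs <- c(outputs, p)
      }
    }
    report$outputs <- outputs
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Validate a study directory and summarize its series
#'
#' @param study_dir study directory.
#' @return list per sequence label: directory, slice count, gap (mm).
#' @export
validate_study <- function(study_dir) {
  layout <- scan_study_dir(study_dir)
  out <- lapply(names(layout$series_dirs), function(label) {
    s <- load_series(layout$series_dirs[[label]])
    list(label = label, dir = layout$series_dirs[[label]],
         count = series_length(s), gap_mm = s$gap)
  })
  names(out) <- names(layout$series_dirs)
  out
}
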