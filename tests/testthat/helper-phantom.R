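# Phantom fixtures shared across test files. The default study (the
# canonical five-sequence protocol) is generated once per test run and
# reused read-only.

.phantom_cache <- new.env(parent = emptyenv())

default_phantom_study <- function() {
  if (is.null(.phantom_cache$dir)) {
    d <- file.path(tempdir(), "carotid3d-default-phantom")
    if (!dir.exists(d)) {
      generate_study(phantom_spec(seed = 42L), d)
    }
    .phantom_cache$dir <- d
  }
  .phantom_cache$dir
}

# a small fast phantom: 64x64 images, short stacks, same two-gap regime
small_phantom_spec <- function(seed = 42L, noise_sd = 20) {
  phantom_spec(
    image_size = c(64L, 64L),
    sequences = data.frame(
      label = c("T1", "T1CE", "T2", "MPRAGE", "TOF"),
      description = c("T1 FS TSE BB", "T1 FS TSE BB CM", "T2 FS TSE BB",
                      "3D MP-RAGE_UW_d8000", "3D TOF Neck"),
      gap = c(2.0, 2.0, 2.0, 0.5, 0.5),
      count = c(6L, 6L, 6L, 24L, 24L),
      start = c(0, 0, 0, 0, 0),
      stringsAsFactors = FALSE
    ),
    noise_sd = noise_sd,
    seed = seed
  )
}

small_phantom_study <- function() {
  if (is.null(.phantom_cache$small)) {
    d <- file.path(tempdir(), "carotid3d-small-phantom")
    if (!dir.exists(d)) {
      generate_study(small_phantom_spec(), d)
    }
    .phantom_cache$small <- d
  }
  .phantom_cache$small
}

# synthetic in-memory study built directly from series objects, for
# registration tests that need arbitrary slice-location geometry without
# touching disk
synthetic_series <- function(label, locations, spacing = c(0.5, 0.5)) {
  slices <- lapply(seq_along(locations), function(i) {
    structure(list(pixel_data = matrix(0L, 2, 2), rows = 2L, cols = 2L,
                   slice_location = locations[i], location_source = "slice_location",
                   pixel_spacing = spacing, series_description = label,
                   study_description = "SYNTH", patient_name = "SYNTH",
                   rescale_slope = 1, rescale_intercept = 0,
                   source_path = sprintf("<mem:%s:%d>", label, i)),
              class = "dicom_slice")
  })
  structure(list(slices = slices, sequence_label = label,
                 gap = if (length(locations) >= 2) median(diff(sort(locations))) else NA_real_,
                 locations = sort(locations)),
            class = "dicom_series")
}

synthetic_study <- function(loc_map) {
  series <- lapply(names(loc_map), function(lbl) synthetic_series(lbl, loc_map[[lbl]]))
  names(series) <- names(loc_map)
  structure(list(layout = NULL, series = series,
                 primary_label = NA_character_, initial_indices = list()),
            class = "carotid_study")
}
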