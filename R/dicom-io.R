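# Study-directory scanning, series loading and display conversion.
#
# Sequence identity comes from the Series Description tag, never from
# folder names. Slices are ordered by the Slice Location tag; a file
# without it falls back to the z component of Image Position (Patient),
# then Instance Number, and mixing fallbacks within one series is an
# error.

SEQUENCE_LABELS <- c("T1", "T1CE", "T2", "TOF", "MPRAGE")

#' Default Series Description classification rules
#'
#' Ordered keyword rules mapping a Series Description string to one of the
#' five sequence labels `T1`, `T1CE`, `T2`, `TOF`, `MPRAGE`. Rules are
#' applied first-match-wins, case-insensitively:
#' \enumerate{
#'   \item contains "MP-RAGE" or "MPRAGE" -> `MPRAGE`
#'   \item contains "TOF" -> `TOF`
#'   \item contains "T2" -> `T2`
#'   \item contains "T1" and ("CM" or "CE") -> `T1CE`
#'   \item contains "T1" -> `T1`
#' }
#'
#' @return a list of rules, each `list(label=, pattern=)`; patterns are
#'   regular expressions matched case-insensitively in order.
#' @export
default_sequence_rules <- function() {
  list(
    list(label = "MPRAGE", pattern = "MP-?RAGE"),
    list(label = "TOF",    pattern = "TOF"),
    list(label = "T2",     pattern = "T2"),
    list(label = "T1CE",   pattern = "T1.*\\b(CM|CE)\\b|\\b(CM|CE)\\b.*T1"),
    list(label = "T1",     pattern = "T1")
  )
}

#' Classify a Series Description string
#'
#' @param description Series Description tag text.
#' @param rules classification rules, see [default_sequence_rules()].
#' @return a sequence label, or `NA_character_` when no rule matches.
#' @export
classify_sequence <- function(description, rules = default_sequence_rules()) {
  for (rule in rules) {
    if (grepl(rule$pattern, description, ignore.case = TRUE)) return(rule$label)
  }
  NA_character_
}

#' Read a single DICOM slice
#'
#' @param path path to a DICOM file.
#' @return a `dicom_slice` object: stored pixel matrix plus the geometry
#'   and identification tags (slice location, pixel spacing, series/study
#'   description, patient name, rescale slope/intercept).
#' @export
read_dicom_slice <- function(path) {
  el <- parse_dicom(path)
  if (is.null(el)) {
    c3d_abort("not_a_dicom", sprintf("not a parsable DICOM file: %s", path))
  }
  rows <- element_get(el, "00280010", function(v) read_uint16(v, 1L))
  cols <- element_get(el, "00280011", function(v) read_uint16(v, 1L))
  if (is.null(rows) || is.null(cols) || rows < 1L || cols < 1L) {
    c3d_abort("format_error", sprintf("missing or invalid Rows/Columns in %s", path))
  }
  px <- el[["7FE00010"]]
  if (is.null(px) || length(px$value) < 2L * rows * cols) {
    c3d_abort("format_error", sprintf("missing or short Pixel Data in %s", path))
  }
  vals <- readBin(px$value, "integer", n = rows * cols, size = 2L,
                  signed = FALSE, endian = "little")
  pixel_data <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  loc <- element_get(el, "00201041", decode_ds)
  loc_source <- "slice_location"
  if (is.null(loc) || length(loc) == 0L) {
    ipp <- element_get(el, "00200032", decode_ds)
    if (!is.null(ipp) && length(ipp) == 3L) {
      loc <- ipp[3]
      loc_source <- "image_position"
    } else {
      inst <- element_get(el, "00200013", function(v) as.numeric(decode_string(v)))
      if (is.null(inst) || is.na(inst)) {
        c3d_abort("format_error",
                  sprintf("no Slice Location, Image Position or Instance Number in %s", path))
      }
      loc <- inst
      loc_source <- "instance_number"
    }
  }
  spacing <- element_get(el, "00280030", decode_ds, default = c(1, 1))
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    c3d_abort("format_error", sprintf("invalid Pixel Spacing in %s", path))
  }
  if (!is.finite(loc[1])) {
    c3d_abort("format_error", sprintf("non-finite slice location in %s", path))
  }

  structure(list(
    pixel_data = pixel_data,
    rows = as.integer(rows),
    cols = as.integer(cols),
    slice_location = loc[1],
    location_source = loc_source,
    pixel_spacing = spacing,
    series_description = element_get(el, "0008103E", decode_string, default = ""),
    study_description = element_get(el, "00081030", decode_string, default = ""),
    patient_name = element_get(el, "00100010", decode_string, default = ""),
    rescale_slope = element_get(el, "00281053", function(v) decode_ds(v)[1], default = 1),
    rescale_intercept = element_get(el, "00281052", function(v) decode_ds(v)[1], default = 0),
    source_path = path
  ), class = "dicom_slice")
}

list_dicom_files <- function(dir) {
  files <- list.files(dir, full.names = TRUE, recursive = FALSE)
  files[!dir.exists(files)]
}

probe_series_description <- function(dir) {
  for (f in sort(list_dicom_files(dir))) {
    el <- tryCatch(parse_dicom(f), error = function(e) NULL)
    if (!is.null(el)) {
      return(element_get(el, "0008103E", decode_string, default = ""))
    }
  }
  NULL
}

#' Scan a study directory and resolve the five sequence sub-directories
#'
#' Probes every immediate sub-directory containing at least one parsable
#' DICOM file and assigns its sequence label by matching the Series
#' Description tag of its first file against the keyword rules. Folder
#' names play no role. Exactly the five labels T1, T1CE, T2, TOF and
#' MPRAGE must resolve; additional sub-directories are ignored with a
#' warning.
#'
#' @param study_dir path to the patient/study directory.
#' @param rules classification rules, see [default_sequence_rules()].
#' @return a `study_layout`: `study_dir`, `series_dirs` (label -> path),
#'   `file_counts` (label -> number of DICOM files).
#' @export
scan_study_dir <- function(study_dir, rules = default_sequence_rules()) {
  if (!dir.exists(study_dir)) {
    c3d_abort("not_a_dicom", sprintf("study directory does not exist: %s", study_dir))
  }
  subdirs <- list.dirs(study_dir, recursive = FALSE)
  series_dirs <- list()
  file_counts <- list()
  for (d in subdirs) {
    desc <- probe_series_description(d)
    if (is.null(desc)) next
    label <- classify_sequence(desc, rules)
    if (is.na(label)) {
      c3d_warn("unclassified_series",
               sprintf("sub-directory %s (Series Description '%s') matches no sequence rule; ignored",
                       basename(d), desc))
      next
    }
    if (!is.null(series_dirs[[label]])) {
      c3d_abort("ambiguous_sequence",
                sprintf("two directories map to sequence %s: %s and %s",
                        label, series_dirs[[label]], d))
    }
    series_dirs[[label]] <- d
    file_counts[[label]] <- length(list_dicom_files(d))
  }
  missing <- setdiff(SEQUENCE_LABELS, names(series_dirs))
  if (length(missing) > 0L) {
    c3d_abort("missing_sequence",
              sprintf("study is missing sequence(s): %s", paste(missing, collapse = ", ")),
              missing = missing)
  }
  structure(list(
    study_dir = study_dir,
    series_dirs = series_dirs[SEQUENCE_LABELS],
    file_counts = file_counts[SEQUENCE_LABELS]
  ), class = "study_layout")
}

#' Load one DICOM series from a directory
#'
#' Reads every parsable DICOM file, orders the slices ascending by slice
#' location, and computes the inter-slice gap as the median of consecutive
#' slice-location differences (robust to one irregular pair). Geometry
#' (rows, columns, pixel spacing) must be homogeneous and slice locations
#' unique.
#'
#' @param series_dir directory containing the series files.
#' @param rules classification rules, see [default_sequence_rules()].
#' @return a `dicom_series`: `slices` (list of `dicom_slice`, ascending),
#'   `sequence_label`, `gap` (mm; `NA` for a single-slice series),
#'   `locations` (numeric vector of slice locations).
#' @export
load_series <- function(series_dir, rules = default_sequence_rules()) {
  files <- sort(list_dicom_files(series_dir))
  slices <- list()
  for (f in files) {
    el <- tryCatch(parse_dicom(f), error = function(e) NULL)
    if (is.null(el)) next
    slices[[length(slices) + 1L]] <- read_dicom_slice(f)
  }
  if (length(slices) == 0L) {
    c3d_abort("not_a_dicom", sprintf("no parsable DICOM file in %s", series_dir))
  }
  sources <- unique(vapply(slices, `[[`, "", "location_source"))
  if (length(sources) > 1L) {
    c3d_abort("inconsistent_geometry",
              sprintf("series %s mixes slice ordering keys: %s",
                      series_dir, paste(sources, collapse = ", ")))
  }
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols, s$pixel_spacing), numeric(4))))
  if (nrow(dims) > 1L) {
    c3d_abort("inconsistent_geometry",
              sprintf("series %s mixes image geometries", series_dir))
  }
  locs <- vapply(slices, `[[`, 0, "slice_location")
  ord <- order(locs)
  slices <- slices[ord]
  locs <- locs[ord]
  if (length(locs) >= 2L && any(diff(locs) < 1e-6)) {
    c3d_abort("duplicate_slice",
              sprintf("series %s has two slices at the same slice location", series_dir))
  }
  gap <- if (length(locs) >= 2L) stats::median(diff(locs)) else NA_real_
  label <- classify_sequence(slices[[1]]$series_description, rules)
  structure(list(
    slices = slices,
    sequence_label = label,
    gap = gap,
    locations = locs
  ), class = "dicom_series")
}

#' Number of slices in a series
#' @param series a `dicom_series`.
#' @return integer slice count.
#' @export
series_length <- function(series) length(series$slices)

#' Scroll-style neighbor index within a series
#'
#' Emulates scrolling through a slice stack: moving past either end clamps
#' at the boundary (no wrap-around).
#'
#' @param series a `dicom_series`.
#' @param current current slice index (1-based).
#' @param direction `"next"` or `"prev"`.
#' @return the neighboring index, clamped to `[1, length]`.
#' @export
neighbor_index <- function(series, current, direction = c("next", "prev")) {
  direction <- match.arg(direction)
  n <- series_length(series)
  if (current < 1L || current > n) {
    c3d_abort("index_error", sprintf("slice index %d out of range [1, %d]", current, n))
  }
  if (direction == "next") min(current + 1L, n) else max(current - 1L, 1L)
}

#' Convert stored pixel values to an 8-bit display raster
#'
#' Applies the rescale slope/intercept, windows the physical values to
#' `[window_min, window_max]`, and maps linearly to `[0, 255]` with
#' round-half-up followed by clamping. The implementation is vectorized
#' but contractually bit-identical to the per-pixel reference loop
#' `clamp(round(255 * (v - wmin) / (wmax - wmin)), 0, 255)`.
#'
#' @param slice a `dicom_slice`.
#' @param window_min,window_max display window bounds on the rescaled
#'   (physical) scale; default to the slice's rescaled min/max.
#' @return integer matrix of the slice's dimensions with values in
#'   `[0, 255]`.
#' @export
convert_to_display <- function(slice, window_min = NULL, window_max = NULL) {
  v <- slice$pixel_data * slice$rescale_slope + slice$rescale_intercept
  if (is.null(window_min)) window_min <- min(v)
  if (is.null(window_max)) window_max <- max(v)
  if (window_max <= window_min) {
    c3d_abort("window_error",
              sprintf("window_max (%g) must exceed window_min (%g)", window_max, window_min))
  }
  scaled <- 255 * (v - window_min) / (window_max - window_min)
  out <- floor(scaled + 0.5)            # round half up
  out[out < 0] <- 0
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}
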