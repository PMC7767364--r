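# Minimal DICOM Part-10 codec: explicit-VR little endian (reading also
# accepts implicit-VR little endian), uncompressed 16-bit monochrome pixel
# data. Covers exactly the tag set this pipeline consumes; it is not a
# general DICOM implementation.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_MR_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"
UID_IMPLEMENTATION <- "1.2.826.0.1.3680043.10.9000.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# implicit-VR needs a tag -> VR dictionary for the tags we handle
DICOM_DICT <- c(
  "00080016" = "UI", "00080018" = "UI", "00080060" = "CS",
  "00081030" = "LO", "0008103E" = "LO",
  "00100010" = "PN",
  "00200013" = "IS", "00200032" = "DS", "00201041" = "DS",
  "00280002" = "US", "00280004" = "CS",
  "00280010" = "US", "00280011" = "US", "00280030" = "DS",
  "00280100" = "US", "00280101" = "US", "00280102" = "US", "00280103" = "US",
  "00281052" = "DS", "00281053" = "DS",
  "7FE00010" = "OW"
)

tag_key <- function(group, elem) {
  sprintf("%04X%04X", group, elem)
}

raw_uint16 <- function(x) {
  x <- as.integer(round(x))
  x <- ifelse(x > 32767L, x - 65536L, x)
  writeBin(x, raw(), size = 2L, endian = "little")
}

raw_uint32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

read_uint16 <- function(buf, at, n = 1L) {
  readBin(buf[at:(at + 2L * n - 1L)], "integer", n = n, size = 2L,
          signed = FALSE, endian = "little")
}

read_uint32 <- function(buf, at) {
  readBin(buf[at:(at + 3L)], "integer", size = 4L, endian = "little")
}

# string values are padded to even length (UI with NUL, text with space)
pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

encode_element <- function(group, elem, vr, value_raw) {
  hdr <- c(raw_uint16(group), raw_uint16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), raw_uint32(length(value_raw)), value_raw)
  } else {
    c(hdr, raw_uint16(length(value_raw)), value_raw)
  }
}

encode_string <- function(group, elem, vr, text) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  encode_element(group, elem, vr, pad_even(charToRaw(text), pad))
}

# DS values: shortest decimal representation that round-trips
format_ds <- function(x) {
  paste(vapply(x, function(v) sprintf("%.10g", v), character(1)), collapse = "\\")
}

#' Write one DICOM file (explicit-VR little endian, 16-bit monochrome)
#'
#' Serializes a single MR slice as an uncompressed DICOM Part-10 file.
#' Only the tags this pipeline relies on are written: Series/Study
#' Description, Patient Name, Slice Location, Image Position (Patient),
#' Instance Number, Pixel Spacing, Rows/Columns, Rescale Slope/Intercept
#' and 16-bit Pixel Data.
#'
#' @param path output file path.
#' @param pixel_data integer matrix (rows x cols) of stored values in
#'   `[0, 65535]`.
#' @param slice_location slice position along the scan axis, mm.
#' @param pixel_spacing numeric length-2, (row_mm, col_mm) per pixel.
#' @param series_description,study_description,patient_name DICOM text tags.
#' @param rescale_slope,rescale_intercept stored-to-physical mapping.
#' @param instance_number integer instance counter within the series.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, pixel_data, slice_location,
                        pixel_spacing = c(0.5, 0.5),
                        series_description = "UNKNOWN",
                        study_description = "SYNTHETIC PHANTOM",
                        patient_name = "PHANTOM^SYNTHETIC",
                        rescale_slope = 1, rescale_intercept = 0,
                        instance_number = 1L) {
  stopifnot(is.matrix(pixel_data), all(is.finite(pixel_data)))
  rows <- nrow(pixel_data)
  cols <- ncol(pixel_data)
  sop_uid <- sprintf("%s.%d.%d", UID_IMPLEMENTATION, instance_number,
                     abs(as.integer(round(slice_location * 1000))) %% 100000L)

  meta_body <- c(
    encode_element(2L, 1L, "OB", as.raw(c(0x00, 0x01))),
    encode_string(2L, 2L, "UI", UID_MR_IMAGE_STORAGE),
    encode_string(2L, 3L, "UI", sop_uid),
    encode_string(2L, 16L, "UI", TS_EXPLICIT_LE),
    encode_string(2L, 18L, "UI", UID_IMPLEMENTATION)
  )
  meta <- c(encode_element(2L, 0L, "UL", raw_uint32(length(meta_body))), meta_body)

  # pixel data row-major (DICOM raster order); R matrices are column-major
  px_raw <- raw_uint16(as.vector(t(pixel_data)))

  dataset <- c(
    encode_string(0x0008L, 0x0016L, "UI", UID_MR_IMAGE_STORAGE),
    encode_string(0x0008L, 0x0018L, "UI", sop_uid),
    encode_string(0x0008L, 0x0060L, "CS", "MR"),
    encode_string(0x0008L, 0x1030L, "LO", study_description),
    encode_string(0x0008L, 0x103EL, "LO", series_description),
    encode_string(0x0010L, 0x0010L, "PN", patient_name),
    encode_string(0x0020L, 0x0013L, "IS", sprintf("%d", as.integer(instance_number))),
    encode_string(0x0020L, 0x0032L, "DS", format_ds(c(0, 0, slice_location))),
    encode_string(0x0020L, 0x1041L, "DS", format_ds(slice_location)),
    encode_element(0x0028L, 0x0002L, "US", raw_uint16(1L)),
    encode_string(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    encode_element(0x0028L, 0x0010L, "US", raw_uint16(rows)),
    encode_element(0x0028L, 0x0011L, "US", raw_uint16(cols)),
    encode_string(0x0028L, 0x0030L, "DS", format_ds(pixel_spacing)),
    encode_element(0x0028L, 0x0100L, "US", raw_uint16(16L)),
    encode_element(0x0028L, 0x0101L, "US", raw_uint16(16L)),
    encode_element(0x0028L, 0x0102L, "US", raw_uint16(15L)),
    encode_element(0x0028L, 0x0103L, "US", raw_uint16(0L)),
    encode_string(0x0028L, 0x1052L, "DS", format_ds(rescale_intercept)),
    encode_string(0x0028L, 0x1053L, "DS", format_ds(rescale_slope)),
    encode_element(0x7FE0L, 0x0010L, "OW", px_raw)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

# Parse one DICOM file into a named list keyed by "GGGGEEEE" hex tag keys.
# Returns NULL when the file lacks the Part-10 magic (not parsable).
parse_dicom <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 140L || rawToChar(buf[129:132]) != "DICM") return(NULL)

  elements <- list()
  pos <- 133L
  explicit <- TRUE
  n <- length(buf)

  while (pos + 7L <= n) {
    group <- read_uint16(buf, pos)
    elem <- read_uint16(buf, pos + 2L)
    key <- tag_key(group, elem)
    pos <- pos + 4L
    in_meta <- group == 2L
    use_explicit <- explicit || in_meta
    if (use_explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- read_uint32(buf, pos + 4L)
        pos <- pos + 8L
      } else {
        len <- read_uint16(buf, pos + 2L)
        pos <- pos + 4L
      }
    } else {
      vr <- if (key %in% names(DICOM_DICT)) DICOM_DICT[[key]] else "UN"
      len <- read_uint32(buf, pos)
      pos <- pos + 4L
    }
    if (len < 0L || pos + len - 1L > n) {
      c3d_abort("format_error", sprintf("corrupt DICOM element %s in %s", key, path))
    }
    value <- if (len > 0L) buf[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len

    if (key == "00020010") {
      ts <- decode_string(value)
      explicit <- !identical(ts, TS_IMPLICIT_LE)
    }
    elements[[key]] <- list(vr = vr, value = value)
  }
  elements
}

decode_string <- function(value) {
  s <- rawToChar(value[value != as.raw(0)])
  sub("[ ]+$", "", s)
}

decode_ds <- function(value) {
  s <- decode_string(value)
  if (!nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}

element_get <- function(elements, key, decoder, default = NULL) {
  el <- elements[[key]]
  if (is.null(el)) return(default)
  decoder(el$value)
}
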