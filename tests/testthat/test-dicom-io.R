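# Study scanning, series loading, scroll emulation and display conversion.

test_that("study scanning classifies series by tag, not folder name", {
  d <- small_phantom_study()
  layout <- scan_study_dir(d)
  expect_setequal(names(layout$series_dirs), c("T1", "T1CE", "T2", "TOF", "MPRAGE"))

  # renamed copies of the same folders classify identically
  d2 <- tempfile("renamed")
  dir.create(d2)
  dirs <- list.dirs(d, recursive = FALSE)
  for (i in seq_along(dirs)) {
    file.copy(dirs[i], d2, recursive = TRUE)
    file.rename(file.path(d2, basename(dirs[i])), file.path(d2, letters[i]))
  }
  layout2 <- scan_study_dir(d2)
  expect_identical(
    lapply(layout$series_dirs, function(p) basename(list.files(p))),
    lapply(layout2$series_dirs, function(p) basename(list.files(p))))
  unlink(d2, recursive = TRUE)
})

test_that("classification follows the ordered keyword rules", {
  expect_identical(classify_sequence("3D MP-RAGE_UW_d8000"), "MPRAGE")
  expect_identical(classify_sequence("3D TOF Neck"), "TOF")
  expect_identical(classify_sequence("T2 FS TSE BB"), "T2")
  expect_identical(classify_sequence("T1 FS TSE BB CM"), "T1CE")
  expect_identical(classify_sequence("T1 FS TSE BB CE"), "T1CE")
  expect_identical(classify_sequence("T1 FS TSE BB"), "T1")
  expect_true(is.na(classify_sequence("LOCALIZER")))
})

test_that("a study with a missing sequence raises MissingSequenceError", {
  d <- small_phantom_study()
  d2 <- tempfile("partial")
  dir.create(d2)
  dirs <- list.dirs(d, recursive = FALSE)
  for (p in dirs[1:4]) file.copy(p, d2, recursive = TRUE)
  expect_error(scan_study_dir(d2), class = "carotid3d_missing_sequence")
  unlink(d2, recursive = TRUE)
})

test_that("series load sorts shuffled files ascending by slice location", {
  d <- small_phantom_study()
  layout <- scan_study_dir(d)
  s <- load_series(layout$series_dirs$T1)
  expect_identical(series_length(s), 6L)
  expect_equal(s$locations, seq(0, 10, by = 2))
  expect_equal(s$gap, 2.0)
  expect_identical(s$sequence_label, "T1")
  # files were written in reverse on-disk order, so sorting did real work
  disk_first <- read_dicom_slice(file.path(layout$series_dirs$T1, "IM0001.dcm"))
  expect_equal(disk_first$slice_location, 10)
})

test_that("load_series is idempotent under re-serialization", {
  d <- small_phantom_study()
  s <- load_series(scan_study_dir(d)$series_dirs$T2)
  d2 <- tempfile("reser")
  dir.create(d2)
  for (i in seq_along(s$slices)) {
    sl <- s$slices[[i]]
    write_dicom(file.path(d2, sprintf("R%03d.dcm", i)), sl$pixel_data,
                slice_location = sl$slice_location,
                pixel_spacing = sl$pixel_spacing,
                series_description = sl$series_description,
                instance_number = i)
  }
  s2 <- load_series(d2)
  expect_equal(s2$locations, s$locations)
  expect_identical(lapply(s2$slices, `[[`, "pixel_data"),
                   lapply(s$slices, `[[`, "pixel_data"))
  unlink(d2, recursive = TRUE)
})

test_that("degenerate series inputs are rejected", {
  d2 <- tempfile("deg")
  dir.create(d2)
  img <- matrix(1:16, 4, 4)
  write_dicom(file.path(d2, "a.dcm"), img, slice_location = 1)
  s <- load_series(d2)
  expect_identical(series_length(s), 1L)
  expect_true(is.na(s$gap))

  write_dicom(file.path(d2, "b.dcm"), img, slice_location = 1)
  expect_error(load_series(d2), class = "carotid3d_duplicate_slice")

  d3 <- tempfile("empty")
  dir.create(d3)
  writeLines("not dicom", file.path(d3, "x.txt"))
  expect_error(load_series(d3), class = "carotid3d_not_a_dicom")
  unlink(c(d2, d3), recursive = TRUE)
})

test_that("neighbor_index clamps at both ends without wrapping", {
  s <- synthetic_series("T1", seq(0, 38, by = 2))
  expect_identical(neighbor_index(s, 1L, "prev"), 1L)
  expect_identical(neighbor_index(s, 20L, "next"), 20L)
  expect_identical(neighbor_index(s, 8L, "next"), 9L)
  expect_identical(neighbor_index(s, 8L, "prev"), 7L)
  expect_error(neighbor_index(s, 0L, "next"), class = "carotid3d_index_error")
  expect_error(neighbor_index(s, 21L, "prev"), class = "carotid3d_index_error")
})

make_slice <- function(pixel, slope = 1, intercept = 0) {
  structure(list(pixel_data = pixel, rows = nrow(pixel), cols = ncol(pixel),
                 slice_location = 0, pixel_spacing = c(0.5, 0.5),
                 series_description = "", study_description = "",
                 patient_name = "", rescale_slope = slope,
                 rescale_intercept = intercept, source_path = ""),
            class = "dicom_slice")
}

test_that("display conversion matches the worked examples", {
  sl <- make_slice(matrix(c(0L, 2048L, 4095L, 1024L), 2, 2))
  out <- convert_to_display(sl, 0, 4095)
  expect_identical(out, matrix(c(0L, 128L, 255L, 64L), 2, 2))

  const <- make_slice(matrix(100L, 3, 3))
  expect_true(all(convert_to_display(const, 0, 100) == 255L))
  expect_error(convert_to_display(const, 50, 50), class = "carotid3d_window_error")
})

test_that("vectorized display conversion is bit-identical to the per-pixel loop", {
  set.seed(101)
  for (rep in 1:10) {
    px <- matrix(sample.int(65536L, 512 * 512, replace = TRUE) - 1L, 512, 512)
    slope <- sample(c(1, 1, 2, 0.5), 1)
    intercept <- sample(c(0, 0, -1024, 10), 1)
    w <- sort(runif(2, min(px) * slope + intercept, max(px) * slope + intercept))
    if (diff(w) < 1) w[2] <- w[1] + 1
    sl <- make_slice(px, slope, intercept)
    expect_identical(convert_to_display(sl, w[1], w[2]),
                     reference_display(px, slope, intercept, w[1], w[2]))
  }
})

test_that("DICOM write-then-read round trip is exact", {
  set.seed(5)
  img <- matrix(sample.int(4096L, 64 * 48, replace = TRUE) - 1L, 48, 64)
  p <- tempfile(fileext = ".dcm")
  write_dicom(p, img, slice_location = 17.25, pixel_spacing = c(0.5, 0.625),
              series_description = "T2 FS TSE BB", instance_number = 3L,
              rescale_slope = 2, rescale_intercept = -1024)
  sl <- read_dicom_slice(p)
  expect_identical(sl$pixel_data, img)
  expect_equal(sl$slice_location, 17.25, tolerance = 1e-9)
  expect_equal(sl$pixel_spacing, c(0.5, 0.625), tolerance = 1e-9)
  expect_identical(sl$series_description, "T2 FS TSE BB")
  expect_equal(sl$rescale_slope, 2)
  expect_equal(sl$rescale_intercept, -1024)
  unlink(p)
})

test_that("pydicom independently parses the phantom's DICOM output", {
  # cross-check the writer against an established reader
  d <- small_phantom_study()
  f <- file.path(scan_study_dir(d)$series_dirs$T1, "IM0003.dcm")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "px = ds.pixel_array",
    "print(json.dumps({'desc': str(ds.SeriesDescription),",
    "  'loc': float(ds.SliceLocation),",
    "  'spacing': [float(x) for x in ds.PixelSpacing],",
    "  'shape': list(px.shape),",
    "  'sum': int(px.sum()), 'first': int(px[0, 0])}))"
  ), script)
  res <- system2("python", c(script, f), stdout = TRUE, stderr = TRUE)
  info <- jsonlite::fromJSON(res[length(res)])
  sl <- read_dicom_slice(f)
  expect_identical(info$desc, sl$series_description)
  expect_equal(info$loc, sl$slice_location)
  expect_equal(info$spacing, sl$pixel_spacing)
  expect_identical(info$shape, c(sl$rows, sl$cols))
  expect_identical(info$sum, sum(sl$pixel_data))
  expect_identical(info$first, sl$pixel_data[1, 1])
  unlink(script)
})
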