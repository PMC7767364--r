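# Primary selection, initial assignment and rationalization.

five_labels <- c("T1", "T1CE", "T2", "TOF", "MPRAGE")

default_geometry <- function() {
  list(T1 = seq(0, 38, by = 2), T1CE = seq(0, 38, by = 2), T2 = seq(0, 38, by = 2),
       TOF = seq(0, 39.5, by = 0.5), MPRAGE = seq(0, 39.5, by = 0.5))
}

test_that("primary selection records the label and rejects unknown ones", {
  study <- synthetic_study(default_geometry())
  study <- select_primary(study, "T1")
  expect_identical(study$primary_label, "T1")
  expect_error(select_primary(study, "T3"), class = "carotid3d_unknown_label")
  expect_error(assign_initial(synthetic_study(default_geometry()), "TOF", 1L),
               class = "carotid3d_primary_not_set")
})

test_that("rationalization requires all four secondary initial slices", {
  study <- select_primary(synthetic_study(default_geometry()), "T1")
  study <- assign_initial(study, "T1CE", 1L)
  study <- assign_initial(study, "T2", 1L)
  study <- assign_initial(study, "TOF", 1L)
  expect_error(rationalize(study), class = "carotid3d_not_ready")
})

test_that("thin-gap sets are decimated onto the primary grid", {
  study <- auto_assign_initial(select_primary(synthetic_study(default_geometry()), "T1"))
  reg <- rationalize(study)
  counts <- vapply(reg$series, series_length, 0L)
  expect_true(all(counts == 20L))
  gaps <- vapply(reg$series, `[[`, 0, "gap")
  expect_true(all(abs(gaps - 2.0) < 1e-6))
  # thin sets keep original slices 1, 5, 9, ..., 77 (locations 0, 2, 4, ...)
  expect_identical(reg$correspondence$TOF, as.integer(seq(1, 77, by = 4)))
  expect_identical(reg$correspondence$MPRAGE, as.integer(seq(1, 77, by = 4)))
  expect_identical(reg$correspondence$T1, 1:20)
})

test_that("identity geometry rationalizes to the identity correspondence", {
  locs <- seq(0, 38, by = 2)
  study <- synthetic_study(setNames(rep(list(locs), 5), five_labels))
  reg <- rationalize(auto_assign_initial(select_primary(study, "T1")))
  for (lbl in five_labels) expect_identical(reg$correspondence[[lbl]], 1:20)
})

test_that("short secondary coverage truncates, or errors when truncation is off", {
  geom <- default_geometry()
  geom$TOF <- seq(0, 19.5, by = 0.5)
  study <- auto_assign_initial(select_primary(synthetic_study(geom), "T1"))
  reg <- rationalize(study)
  expect_identical(length(reg$locations), 10L)
  expect_true(all(vapply(reg$series, series_length, 0L) == 10L))
  expect_error(rationalize(study, registration_config(allow_truncation = FALSE)),
               class = "carotid3d_incompatible_primary")
})

test_that("a thin-gap primary with thick-gap secondaries is incompatible", {
  study <- auto_assign_initial(select_primary(synthetic_study(default_geometry()), "MPRAGE"))
  expect_error(rationalize(study), class = "carotid3d_incompatible_primary")
})

test_that("auto initial assignment picks the nearest slice location", {
  geom <- default_geometry()
  geom$TOF <- geom$TOF + 0.3   # offset start
  study <- auto_assign_initial(select_primary(synthetic_study(geom), "T1"))
  # brute force: nearest of TOF locations to primary location 0
  expect_identical(study$initial_indices$TOF,
                   which.min(abs(geom$TOF - 0)))
})

test_that("rationalization is idempotent and correspondence is monotone", {
  set.seed(202)
  for (rep in 1:10) {
    # draw gap pairs whose ratio is integral, so a uniform common grid exists
    pair <- sample(list(c(2.0, 0.4), c(2.0, 0.5), c(2.0, 1.0), c(2.5, 0.5)), 1)[[1]]
    thick_gap <- pair[1]; thin_gap <- pair[2]
    n_thick <- 12L
    span <- thick_gap * (n_thick - 1L)
    thin_locs <- seq(0, span + thin_gap, by = thin_gap)
    geom <- list(
      T1 = thick_gap * (0:(n_thick - 1L)),
      T1CE = thick_gap * (0:(n_thick - 1L)) + runif(1, 0, thick_gap),
      T2 = thick_gap * (0:(n_thick - 1L)),
      TOF = thin_locs + runif(1, 0, thin_gap),
      MPRAGE = thin_locs
    )
    study <- auto_assign_initial(select_primary(synthetic_study(geom), "T1"))
    reg <- rationalize(study)
    counts <- vapply(reg$series, series_length, 0L)
    expect_true(all(counts == counts[1]))
    gaps <- vapply(reg$series, `[[`, 0, "gap")
    expect_true(all(abs(gaps - gaps["T1"]) < 1e-6))
    for (lbl in five_labels) {
      expect_true(all(diff(reg$correspondence[[lbl]]) > 0))
    }
    # re-rationalizing the retained geometry is the identity
    study2 <- synthetic_study(lapply(reg$series, `[[`, "locations"))
    reg2 <- rationalize(auto_assign_initial(select_primary(study2, "T1")))
    for (lbl in five_labels) {
      expect_identical(reg2$correspondence[[lbl]], seq_len(counts[1]))
    }
  }
})

test_that("incommensurate gaps cannot be rationalized to a uniform grid", {
  # 1.8 mm primary with a 0.5 mm secondary: no decimation yields equal gaps
  geom <- list(T1 = 1.8 * (0:9), T1CE = 1.8 * (0:9), T2 = 1.8 * (0:9),
               TOF = 0.5 * (0:39), MPRAGE = 0.5 * (0:39))
  study <- auto_assign_initial(select_primary(synthetic_study(geom), "T1"))
  expect_error(rationalize(study), class = "carotid3d_incompatible_primary")
})

test_that("nearest-location decimation matches the exhaustive subsequence oracle", {
  set.seed(303)
  for (rep in 1:50) {
    thin_gap <- sample(c(0.4, 0.5, 1.0), 1)
    n_thin <- sample(8:12, 1)
    offset <- runif(1, 0, thin_gap)
    thin_locs <- thin_gap * (0:(n_thin - 1L)) + offset
    thick_gap <- 2.0
    n_thick <- max(2L, min(6L, floor((max(thin_locs) - offset) / thick_gap) + 1L))
    thick_locs <- thick_gap * (0:(n_thick - 1L))
    geom <- list(T1 = thick_locs, T1CE = thick_locs, T2 = thick_locs,
                 TOF = thin_locs, MPRAGE = thin_locs)
    study <- auto_assign_initial(select_primary(synthetic_study(geom), "T1"))
    reg <- rationalize(study)
    m <- length(reg$locations)
    s0 <- study$initial_indices$TOF
    targets <- reg$locations + (thin_locs[s0] - thick_locs[1])
    oracle <- brute_force_decimation(thin_locs, targets)
    expect_identical(reg$correspondence$TOF, as.integer(oracle))
  }
})

test_that("the default phantom study rationalizes to the expected grid", {
  d <- default_phantom_study()
  study <- auto_assign_initial(select_primary(load_study(d), "T1"))
  reg <- rationalize(study)
  expect_identical(length(reg$locations), 20L)
  expect_equal(reg$gap, 2.0, tolerance = 1e-9)
  for (lbl in five_labels) {
    dev <- abs(reg$series[[lbl]]$locations - reg$offsets[[lbl]] - reg$locations)
    expect_true(all(dev <= 0.25))
  }
})
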