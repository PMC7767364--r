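# Slice-location registration: primary selection, initial-slice
# assignment in the secondary sets, and rationalization of all five
# series to equal counts, equal gaps and aligned slice locations.
#
# Alignment is purely Slice Location arithmetic: thin-gap series (3D
# acquisitions such as TOF and MP-RAGE) are decimated onto the primary
# grid by nearest slice location; thick-gap series are retained
# one-for-one from the assigned initial slice. No intensity-based or
# in-plane registration is performed.

#' Registration configuration
#'
#' @param gap_threshold gap (mm) separating "thin" 3D acquisitions from
#'   "thick" spin-echo stacks; series with a gap below the threshold are
#'   decimated onto the primary grid. Default 1.8 mm.
#' @param location_tolerance maximum slice-location disagreement (mm)
#'   tolerated at each retained position. `NULL` (default) means half the
#'   primary gap, resolved at rationalization time.
#' @param allow_truncation when secondary coverage is shorter than the
#'   primary's, truncate all series to common coverage instead of
#'   raising an error. Default `TRUE`.
#' @return a `registration_config` list.
#' @export
registration_config <- function(gap_threshold = 1.8, location_tolerance = NULL,
                                allow_truncation = TRUE) {
  if (gap_threshold <= 0) c3d_abort("domain_error", "gap_threshold must be > 0")
  if (!is.null(location_tolerance) && location_tolerance <= 0) {
    c3d_abort("domain_error", "location_tolerance must be > 0")
  }
  structure(list(gap_threshold = gap_threshold,
                 location_tolerance = location_tolerance,
                 allow_truncation = allow_truncation),
            class = "registration_config")
}

#' Load the five series of a study
#'
#' @param study_dir study directory (see [scan_study_dir()]).
#' @param rules sequence classification rules.
#' @return a `carotid_study`: `layout`, `series` (label -> `dicom_series`),
#'   `primary_label` (`NA` until selected), `initial_indices`.
#' @export
load_study <- function(study_dir, rules = default_sequence_rules()) {
  layout <- scan_study_dir(study_dir, rules)
  series <- lapply(layout$series_dirs, load_series, rules = rules)
  structure(list(layout = layout, series = series,
                 primary_label = NA_character_,
                 initial_indices = list()),
            class = "carotid_study")
}

#' Select the primary sequence set
#'
#' The primary set is the one on which lumen/wall marking is performed;
#' markings are later reproduced on the secondary sets. No series is
#' modified.
#'
#' @param study a `carotid_study`.
#' @param label one of the five loaded sequence labels.
#' @return the study with `primary_label` recorded and its own initial
#'   index fixed at 1.
#' @export
select_primary <- function(study, label) {
  if (!label %in% names(study$series)) {
    c3d_abort("unknown_label", sprintf("unknown sequence label: %s", label))
  }
  study$primary_label <- label
  study$initial_indices <- list()
  study$initial_indices[[label]] <- 1L
  study
}

#' Assign the initial (number 1) slice of a secondary series
#'
#' @param study a `carotid_study` with the primary already selected.
#' @param label a secondary sequence label.
#' @param index slice index (1-based) of the slice that corresponds to the
#'   primary's first slice.
#' @return the study with the assignment recorded.
#' @export
assign_initial <- function(study, label, index) {
  if (is.na(study$primary_label)) {
    c3d_abort("primary_not_set", "select the primary series before assigning initial slices")
  }
  if (!label %in% names(study$series)) {
    c3d_abort("unknown_label", sprintf("unknown sequence label: %s", label))
  }
  n <- series_length(study$series[[label]])
  index <- as.integer(index)
  if (index < 1L || index > n) {
    c3d_abort("index_error", sprintf("initial index %d out of range [1, %d] for %s",
                                     index, n, label))
  }
  study$initial_indices[[label]] <- index
  study
}

#' Auto-assign initial slices by nearest slice location
#'
#' For every secondary series, chooses the slice whose slice location is
#' nearest the primary's first slice location (ties: lower index).
#'
#' @param study a `carotid_study` with the primary selected.
#' @return the study with all four secondary assignments recorded.
#' @export
auto_assign_initial <- function(study) {
  if (is.na(study$primary_label)) {
    c3d_abort("primary_not_set", "select the primary series first")
  }
  target <- study$series[[study$primary_label]]$locations[1]
  for (label in setdiff(names(study$series), study$primary_label)) {
    d <- abs(study$series[[label]]$locations - target)
    study <- assign_initial(study, label, which.min(d))
  }
  study
}

subset_series <- function(series, idx) {
  series$slices <- series$slices[idx]
  series$locations <- series$locations[idx]
  series$gap <- if (length(idx) >= 2L) stats::median(diff(series$locations)) else NA_real_
  series
}

#' Rationalize a study to equal counts, gaps and aligned locations
#'
#' Starting from each secondary's assigned initial slice, thin-gap series
#' (gap below `gap_threshold` while the primary gap is at or above it) are
#' decimated by keeping, for each primary position, the original slice
#' whose location is nearest the primary location plus the per-series
#' offset (offset = initial secondary location minus initial primary
#' location; ties keep the lower index). Thick-gap series are retained
#' one-for-one from the initial slice. A secondary contributes positions
#' only while the target location stays inside its coverage span and the
#' nearest slice lies within `location_tolerance`; all series are then
#' truncated to the shortest resulting length.
#'
#' @param study a `carotid_study` with primary and all four secondary
#'   initial slices assigned.
#' @param config a [registration_config()].
#' @return a `registered_study`: `primary_label`, `series` (rationalized),
#'   `initial_indices`, `offsets`, `correspondence` (data frame, one row
#'   per retained position, one column per label holding the original
#'   slice index), `locations` (primary retained slice locations), `gap`.
#' @export
rationalize <- function(study, config = registration_config()) {
  if (is.na(study$primary_label)) {
    c3d_abort("primary_not_set", "select the primary series first")
  }
  secondaries <- setdiff(names(study$series), study$primary_label)
  unassigned <- setdiff(secondaries, names(study$initial_indices))
  if (length(unassigned) > 0L) {
    c3d_abort("not_ready",
              sprintf("initial slice not assigned for: %s", paste(unassigned, collapse = ", ")))
  }

  primary <- study$series[[study$primary_label]]
  p0 <- study$initial_indices[[study$primary_label]]
  prim_idx <- seq.int(p0, series_length(primary))
  prim_loc <- primary$locations[prim_idx]
  prim_gap <- primary$gap
  tol <- if (is.null(config$location_tolerance)) prim_gap / 2 else config$location_tolerance
  if (!is.finite(tol) || tol <= 0) {
    c3d_abort("domain_error", "location tolerance is undefined (single-slice primary?)")
  }

  offsets <- stats::setNames(numeric(length(study$series)), names(study$series))
  retained <- list()
  retained[[study$primary_label]] <- prim_idx

  for (label in secondaries) {
    sec <- study$series[[label]]
    s0 <- study$initial_indices[[label]]
    offset <- sec$locations[s0] - prim_loc[1]
    offsets[[label]] <- offset
    span <- range(sec$locations)
    thin <- is.finite(sec$gap) && sec$gap < config$gap_threshold &&
      is.finite(prim_gap) && prim_gap >= config$gap_threshold

    idx <- integer(0)
    last <- if (thin) 0L else s0 - 1L
    for (k in seq_along(prim_loc)) {
      target <- prim_loc[k] + offset
      if (target < span[1] - 1e-6 || target > span[2] + 1e-6) break
      if (thin) {
        cand <- seq.int(last + 1L, length(sec$locations))
        if (length(cand) == 0L) break
        d <- abs(sec$locations[cand] - target)
        j <- cand[which.min(d)]          # which.min keeps the lower index on ties
      } else {
        j <- last + 1L
        if (j > length(sec$locations)) break
      }
      if (abs(sec$locations[j] - target) > tol) break
      idx <- c(idx, j)
      last <- j
    }
    if (length(idx) == 0L) {
      c3d_abort("incompatible_primary",
                sprintf("series %s cannot supply any slice within %.3g mm of the primary grid",
                        label, tol))
    }
    retained[[label]] <- idx
  }

  n_keep <- min(vapply(retained, length, 0L))
  if (n_keep < 2L) {
    c3d_abort("incompatible_primary",
              "fewer than two common positions remain; the chosen primary grid is incompatible with the secondaries")
  }
  if (!config$allow_truncation && n_keep < length(prim_idx)) {
    short <- names(retained)[vapply(retained, length, 0L) < length(prim_idx)]
    c3d_abort("incompatible_primary",
              sprintf("series %s cover fewer positions than the primary and truncation is disabled",
                      paste(short, collapse = ", ")))
  }
  retained <- lapply(retained, function(ix) ix[seq_len(n_keep)])

  out_series <- list()
  for (label in names(study$series)) {
    out_series[[label]] <- subset_series(study$series[[label]], retained[[label]])
  }

  # enforce the registered-study invariants: equal gaps and aligned locations
  gaps <- vapply(out_series, `[[`, 0, "gap")
  if (n_keep >= 2L) {
    bad <- names(gaps)[abs(gaps - gaps[[study$primary_label]]) > 1e-6]
    if (length(bad) > 0L) {
      c3d_abort("incompatible_primary",
                sprintf("gap mismatch after rationalization (primary %.4g mm): %s",
                        gaps[[study$primary_label]],
                        paste(sprintf("%s=%.4g", bad, gaps[bad]), collapse = ", ")))
    }
  }
  for (label in secondaries) {
    dev <- abs(out_series[[label]]$locations - offsets[[label]] -
                 out_series[[study$primary_label]]$locations)
    if (any(dev > tol + 1e-9)) {
      c3d_abort("incompatible_primary",
                sprintf("series %s deviates from the primary grid by up to %.3g mm (tolerance %.3g)",
                        label, max(dev), tol))
    }
  }

  corr <- as.data.frame(retained)[names(study$series)]
  structure(list(
    primary_label = study$primary_label,
    series = out_series,
    initial_indices = study$initial_indices,
    offsets = offsets,
    correspondence = corr,
    locations = out_series[[study$primary_label]]$locations,
    gap = out_series[[study$primary_label]]$gap,
    location_tolerance = tol
  ), class = "registered_study")
}
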