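# Structured error conditions. Every error raised by the package carries a
# class of the form "carotid3d_<snake_name>" plus "carotid3d_error", so
# callers (and tests) can discriminate failure modes programmatically.

c3d_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("carotid3d_", class), "carotid3d_error")))
}

c3d_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(paste0("carotid3d_", class), "carotid3d_warning")))
}

#' @title Error classes used by carotid3d
#' @description
#' All errors signalled by the package are classed conditions. The class
#' names, in the form `carotid3d_<name>`, are:
#' `missing_sequence`, `ambiguous_sequence`, `not_a_dicom`,
#' `duplicate_slice`, `inconsistent_geometry`, `window_error`,
#' `index_error`, `unknown_label`, `primary_not_set`, `not_ready`,
#' `incompatible_primary`, `layer_closed`, `layer_open`,
#' `too_few_points`, `bounds_error`, `degenerate_edge`, `domain_error`,
#' `too_few_layers`, `non_monotone_z`, `open_mesh`,
#' `unsupported_format`, `format_error`, `unregistered_slice`.
#' @name carotid3d-conditions
#' @keywords internal
NULL
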