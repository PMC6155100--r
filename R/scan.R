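# Per-scan container: one subject-paradigm node time series plus nuisance.

#' Construct a scan time-series object
#'
#' @param data Numeric node-by-timepoint matrix.
#' @param subject_id,paradigm Identifiers.
#' @param sampling_interval Repetition time in seconds.
#' @param nuisance Timepoint-by-regressor matrix (task regressors, tissue
#'   signals, motion expansion, frame-wise displacement), or `NULL`.
#' @return A list of class `scan_ts`.
#' @export
scan_ts <- function(data, subject_id, paradigm, sampling_interval = 2,
                    nuisance = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    abort("scan data must be a finite numeric matrix (nodes x timepoints)")
  }
  n_t <- ncol(data)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_t) {
      abort(sprintf("nuisance has %d rows but the scan has %d timepoints",
                    nrow(nuisance), n_t))
    }
    if (any(!is.finite(nuisance))) abort("nuisance contains non-finite values")
    # +1 for the implicit intercept added at regression time
    if (n_t < 2 * (ncol(nuisance) + 1L)) {
      abort("timepoints must be at least twice the regressor count")
    }
  }
  structure(list(subject_id = as.character(subject_id),
                 paradigm = as.character(paradigm),
                 data = data,
                 sampling_interval = as.numeric(sampling_interval),
                 nuisance = nuisance),
            class = "scan_ts")
}

#' @export
print.scan_ts <- function(x, ...) {
  cat(sprintf("<scan_ts> subject %s, paradigm %s: %d nodes x %d timepoints (TR %gs, %d nuisance cols)\n",
              x$subject_id, x$paradigm, nrow(x$data), ncol(x$data),
              x$sampling_interval,
              if (is.null(x$nuisance)) 0L else ncol(x$nuisance)))
  invisible(x)
}
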