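# Node time series -> per-scan connectivity matrices.
#
# Processing contract: nuisance regression first, then temporal filtering,
# then pairwise Pearson correlation of the cleaned series.

#' Regress nuisance signals out of a scan
#'
#' Removes the least-squares fit of each node series on an intercept plus
#' the scan's nuisance regressors (task regressors, tissue signals, motion
#' expansion, frame-wise displacement). Residuals are orthogonal to every
#' retained regressor. Collinear nuisance columns are dropped with a warning
#' naming them.
#'
#' @param scan A [scan_ts()].
#' @param tol Relative tolerance for detecting rank deficiency.
#' @return The scan with residual data and an attribute
#'   `dropped_regressors` listing any removed columns.
#' @export
regress_nuisance <- function(scan, tol = 1e-10) {
  stopifnot(inherits(scan, "scan_ts"))
  y <- t(scan$data)                       # timepoints x nodes
  n_t <- nrow(y)
  x <- cbind(intercept = rep(1, n_t), scan$nuisance)
  qr_x <- qr(x, tol = tol)
  dropped <- character(0)
  if (qr_x$rank < ncol(x)) {
    keep_cols <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(x)[-keep_cols]
    dropped[is.na(dropped) | dropped == ""] <-
      paste0("column", which(is.na(colnames(x)) | colnames(x) == ""))
    warn(sprintf("dropping collinear nuisance column(s): %s",
                 paste(dropped, collapse = ", ")))
    x <- x[, keep_cols, drop = FALSE]
    qr_x <- qr(x, tol = tol)
  }
  resid <- qr.resid(qr_x, y)
  out <- scan
  out$data <- t(resid)
  out$nuisance <- if (ncol(x) > 1L) x[, -1L, drop = FALSE] else NULL
  attr(out, "dropped_regressors") <- dropped
  out
}

#' Temporally filter a scan
#'
#' Zero-phase (forward-backward) Butterworth filtering of each node series.
#' `high_hz = Inf` gives a high-pass filter; `low_hz = 0` a low-pass. The
#' contract is spectral: stop-band attenuation of at least 20 dB and
#' pass-band gain within 10 percent, which the default order satisfies for
#' the conventional rest (0.008-0.1 Hz band-pass) and task (0.008 Hz
#' high-pass) settings.
#'
#' @param scan A [scan_ts()].
#' @param low_hz,high_hz Band edges in Hz; `0 <= low_hz < high_hz`, and
#'   `high_hz` at most the Nyquist frequency (or `Inf`).
#' @param order Butterworth order of the one-pass prototype (doubled by the
#'   forward-backward application).
#' @return The filtered scan.
#' @export
temporal_filter <- function(scan, low_hz = 0.008, high_hz = 0.1, order = 2) {
  stopifnot(inherits(scan, "scan_ts"))
  fs <- 1 / scan$sampling_interval
  nyq <- fs / 2
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz < 0 ||
      low_hz >= high_hz) {
    abort("need 0 <= low_hz < high_hz")
  }
  if (low_hz >= nyq || (is.finite(high_hz) && high_hz > nyq)) {
    abort(sprintf("band [%g, %g] Hz lies outside the Nyquist range (0, %g] Hz",
                  low_hz, high_hz, nyq))
  }
  filt <- if (low_hz > 0 && is.finite(high_hz)) {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else if (low_hz > 0) {
    signal::butter(order, low_hz / nyq, type = "high")
  } else {
    signal::butter(order, high_hz / nyq, type = "low")
  }
  y <- t(scan$data)
  if (low_hz > 0) {
    # the pass band excludes DC: remove means exactly before filtering
    # (also tames forward-backward edge transients)
    y <- sweep(y, 2L, colMeans(y))
  }
  filtered <- vapply(seq_len(ncol(y)), function(i) {
    signal::filtfilt(filt, y[, i])
  }, numeric(nrow(y)))
  out <- scan
  out$data <- t(filtered)
  out
}

#' Compute a connectivity matrix from a scan
#'
#' Pairwise Pearson correlations between the node series.
#'
#' @param scan A [scan_ts()] (typically after [regress_nuisance()] and
#'   [temporal_filter()]).
#' @return A symmetric unit-diagonal node-by-node matrix of class
#'   `connectivity_matrix`.
#' @export
compute_connectivity <- function(scan) {
  stopifnot(inherits(scan, "scan_ts"))
  y <- t(scan$data)
  v <- apply(y, 2L, var)
  if (any(v <= .Machine$double.eps)) {
    abort(sprintf("node(s) with zero variance: %s",
                  paste(which(v <= .Machine$double.eps) - 1L, collapse = ", ")))
  }
  m <- cor(y)
  m[abs(m) > 1] <- sign(m[abs(m) > 1])   # guard numeric overshoot
  diag(m) <- 1
  dimnames(m) <- NULL
  structure(m, class = c("connectivity_matrix", "matrix", "array"),
            node_ids = 0:(nrow(m) - 1L))
}

#' Vectorize a connectivity matrix to its canonical edge vector
#'
#' Row-major upper triangle (0-based node ids, i < j); see [edge_table()].
#'
#' @param m Symmetric unit-diagonal matrix.
#' @param tol Maximum tolerated asymmetry.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  m <- unclass(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    abort("matrix is not symmetric within tolerance")
  }
  extract_edges(m)
}

#' @rdname vectorize_edges
#' @param v Edge vector in canonical order.
#' @param diagonal Value placed on the diagonal of the restored matrix.
#' @export
devectorize_edges <- function(v, diagonal = 1) {
  e <- length(v)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (n != floor(n)) abort("edge vector length is not n(n-1)/2 for integer n")
  m <- devectorize_z(v, as.integer(n))
  diag(m) <- diagonal
  m
}

#' Connectivity matrices for every scan of a cohort
#'
#' Runs the processing chain (optional nuisance regression, optional
#' temporal filtering, Pearson correlation) over all scans and returns the
#' edge vectors.
#'
#' @param cohort A `synthetic_cohort` (or any list with `scans` and
#'   `scan_index` of the same shape).
#' @param regress Apply [regress_nuisance()] per scan.
#' @param filter One of "none", "rest" (band-pass 0.008-0.1 Hz), "task"
#'   (high-pass 0.008 Hz).
#' @param fisher_z Apply `atanh` to the edge values.
#' @return A list with `edges` (scan-by-edge matrix, rows named as
#'   `scan_index$scan`) and `scan_index`.
#' @export
cohort_connectivity <- function(cohort, regress = TRUE,
                                filter = c("none", "rest", "task"),
                                fisher_z = FALSE) {
  filter <- match.arg(filter)
  scans <- cohort$scans
  e_total <- n_edges_for(nrow(scans[[1L]]$data))
  edges <- matrix(NA_real_, length(scans), e_total,
                  dimnames = list(names(scans), NULL))
  for (nm in names(scans)) {
    sc <- scans[[nm]]
    if (regress) sc <- regress_nuisance(sc)
    if (filter == "rest") sc <- temporal_filter(sc, 0.008, 0.1)
    if (filter == "task") sc <- temporal_filter(sc, 0.008, Inf)
    edges[nm, ] <- vectorize_edges(compute_connectivity(sc))
  }
  if (fisher_z) edges <- atanh(pmin(pmax(edges, -1 + 1e-12), 1 - 1e-12))
  list(edges = edges, scan_index = cohort$scan_index)
}
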