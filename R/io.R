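# Plain-text interchange: TSV readers/writers with schema validation.
# Node ids are 0-based everywhere; all tables are tab-separated.

sample_sheet_cols <- c("subject_id", "group", "age", "sex", "iq", "site",
                       "fd", "dose")
phenotype_cols <- c("subject_id", "symptom_positive",
                    "symptom_disorganization", "months_to_conversion",
                    "follow_up_months")

#' Read and validate a sample sheet
#'
#' @param path TSV with columns `r paste(sample_sheet_cols, collapse = ", ")`.
#' @param group_levels Ordered group levels; defaults to order of appearance.
#' @return A tibble with `group` as an ordered factor.
#' @export
read_sample_sheet <- function(path, group_levels = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, sample_sheet_cols, sprintf("sample sheet '%s'", path))
  if (is.null(group_levels)) group_levels <- unique(df$group)
  df$group <- factor(df$group, levels = group_levels, ordered = TRUE)
  if (anyNA(df$group)) abort("sample sheet contains groups outside group_levels")
  bad <- which(!complete.cases(df[, sample_sheet_cols]))
  if (length(bad) > 0) {
    abort(sprintf("sample sheet '%s' has incomplete row(s): %s",
                  path, paste(head(bad, 5) + 1L, collapse = ", ")))
  }
  df
}

#' Read and validate a phenotype table
#'
#' `months_to_conversion` may be missing (NA) but must be positive where
#' present.
#'
#' @param path TSV with columns `r paste(phenotype_cols, collapse = ", ")`.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, phenotype_cols, sprintf("phenotype table '%s'", path))
  bad <- which(!is.na(df$months_to_conversion) & df$months_to_conversion <= 0)
  if (length(bad) > 0) {
    abort(sprintf("phenotype table '%s': months_to_conversion must be > 0 (row(s) %s)",
                  path, paste(head(bad, 5) + 1L, collapse = ", ")))
  }
  df
}

#' Read a symmetric matrix TSV
#'
#' @param path TSV of a square numeric matrix (no header, no row names).
#' @param tol Maximum tolerated asymmetry.
#' @return A numeric matrix.
#' @export
read_matrix_tsv <- function(path, tol = 1e-8) {
  m <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                 show_col_types = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    abort(sprintf("'%s' is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    abort(sprintf("'%s' is asymmetric at (%d, %d): |%g - %g| > %g", path,
                  ij[1L], ij[2L], m[ij[1L], ij[2L]], m[ij[2L], ij[1L]], tol))
  }
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix to write.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(unclass(m), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write an edge-list TSV as a network mask
#'
#' @param path TSV with columns `node_i`, `node_j` (0-based) and optionally
#'   `effect`.
#' @param n_nodes Atlas size.
#' @return A [network_mask()].
#' @export
read_edge_list <- function(path, n_nodes) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("node_i", "node_j"), sprintf("edge list '%s'", path))
  network_mask(df, n_nodes)
}

#' @rdname read_edge_list
#' @param mask Mask to write.
#' @param effect Optional per-edge values written as an `effect` column.
#' @export
write_edge_list <- function(mask, path, effect = NULL) {
  out <- as_tibble(mask)
  if (!is.null(effect)) out$effect <- effect
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write/read a synthetic cohort as plain-text files
#'
#' Layout: `sample_sheet.tsv`, `phenotypes.tsv`, `truth_edges.tsv`, and one
#' `scans/<subject>.<paradigm>.tsv` (nodes x timepoints, no header) plus
#' `scans/<subject>.<paradigm>.nuisance.tsv` per scan.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly ([write_cohort()]); a `synthetic_cohort`-shaped
#'   list ([read_cohort()]).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$design, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_edge_list(cohort$truth$mask, file.path(dir, "truth_edges.tsv"),
                  effect = rep(cohort$truth$delta_z[length(cohort$truth$delta_z)],
                               nrow(cohort$truth$mask)))
  readr::write_tsv(cohort$scan_index, file.path(dir, "scan_index.tsv"))
  for (nm in names(cohort$scans)) {
    sc <- cohort$scans[[nm]]
    write_matrix_tsv(sc$data, file.path(dir, "scans", paste0(nm, ".tsv")))
    utils::write.table(sc$nuisance,
                       file.path(dir, "scans", paste0(nm, ".nuisance.tsv")),
                       sep = "\t", row.names = FALSE)
  }
  meta <- list(n_nodes = cohort$config$n_nodes,
               sampling_interval = cohort$config$sampling_interval,
               group_levels = names(cohort$config$group_sizes))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  design <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"),
                              group_levels = meta$group_levels)
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  scan_index <- readr::read_tsv(file.path(dir, "scan_index.tsv"),
                                show_col_types = FALSE)
  truth_mask <- read_edge_list(file.path(dir, "truth_edges.tsv"),
                               n_nodes = meta$n_nodes)
  scans <- lapply(seq_len(nrow(scan_index)), function(i) {
    nm <- scan_index$scan[i]
    data <- as.matrix(readr::read_tsv(
      file.path(dir, "scans", paste0(nm, ".tsv")),
      col_names = FALSE, show_col_types = FALSE))
    dimnames(data) <- NULL
    nuis <- as.matrix(readr::read_tsv(
      file.path(dir, "scans", paste0(nm, ".nuisance.tsv")),
      show_col_types = FALSE))
    scan_ts(data, scan_index$subject_id[i], scan_index$paradigm[i],
            sampling_interval = meta$sampling_interval, nuisance = nuis)
  })
  names(scans) <- scan_index$scan
  structure(list(scans = scans, scan_index = scan_index, design = design,
                 phenotypes = phenotypes,
                 truth = list(mask = truth_mask)),
            class = "synthetic_cohort")
}
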