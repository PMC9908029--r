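#' Read and write 10x-style sparse count matrices
#'
#' The on-disk convention is a directory holding `matrix.mtx` (Matrix
#' Market coordinate format, 1-based indices), `features.tsv` (one feature
#' id per line) and `barcodes.tsv` (one cell barcode per line).
#'
#' @param counts Genes x cells sparse matrix with dimnames.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_counts_mtx()` returns `dir` invisibly;
#'   `read_counts_mtx()` returns a `dgCMatrix` with feature rownames and
#'   barcode colnames.
#' @export
write_counts_mtx <- function(counts, dir) {
  assert_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  if (!all(file.exists(paths))) {
    stop_input(paste0("expected matrix.mtx + features.tsv + barcodes.tsv in ", dir))
  }
  m <- as(readMM(paths[1]), "CsparseMatrix")
  m <- as(m, "dgCMatrix")
  dimnames(m) <- list(readLines(paths[2]), readLines(paths[3]))
  m
}

#' Read and write signed gene signatures
#'
#' A signed signature is a tibble with columns `gene` and `direction`
#' (`+1` up-regulated, `-1` down-regulated). The TSV layout is two
#' columns without header; GMT files (one set per line:
#' `name <tab> description <tab> gene...`) carry unsigned sets, read back
#' with `direction = +1`.
#'
#' @param signature Tibble with `gene` and `direction` columns.
#' @param path File path.
#' @return `read_signature_tsv()` returns the signature tibble;
#'   `read_gmt()` a named list of unsigned signature tibbles.
#' @export
write_signature_tsv <- function(signature, path) {
  stopifnot(all(c("gene", "direction") %in% names(signature)))
  utils::write.table(signature[, c("gene", "direction")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signature_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "direction"),
                         colClasses = c("character", "integer"))
  if (!all(x$direction %in% c(-1L, 1L))) {
    stop_input("signature directions must be +1 or -1")
  }
  as_tibble(x)
}

#' @rdname write_signature_tsv
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    tibble(gene = f[-(1:2)], direction = 1L)
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

#' Read a patient cohort table
#'
#' Expected CSV layout: first column `patient_id`, second `status`
#' (`live`/`dead`), remaining columns gene log-expression.
#'
#' @param path CSV file path.
#' @return A cohort tibble as produced by [simulate_cohort()].
#' @export
read_cohort_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!all(c("patient_id", "status") %in% names(x)[1:2])) {
    stop_input("cohort CSV must start with columns `patient_id`, `status`")
  }
  bad <- setdiff(unique(x$status), c("live", "dead"))
  if (length(bad) > 0L) stop_input("`status` must be 'live' or 'dead'")
  x
}

#' Read a per-cell imaging table
#'
#' @param path CSV with columns `plate, well, compound, dose_um, cell_id,
#'   int_myog, int_ki67, int_myhc`.
#' @return A tibble of per-cell imaging records.
#' @export
read_cell_table_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path, check.names = FALSE))
  need <- c("plate", "well", "compound", "dose_um", "cell_id", MYO_MARKERS)
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop_input(paste0("cell table lacks column(s): ",
                      paste(missing, collapse = ", ")))
  }
  x
}
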