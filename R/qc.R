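#' Per-cell quality-control metrics
#'
#' Computes, for every cell of a genes x cells count matrix, the number of
#' detected genes (features with count > 0), the total UMI count, and the
#' percentage of UMIs mapping to mitochondrial features.
#'
#' @param counts Genes x cells sparse count matrix with dimnames.
#' @param mito_features Character vector of mitochondrial feature ids, or
#'   `NULL` to match by `mito_prefix`. Features absent from `counts` are
#'   ignored; an empty mitochondrial set yields `mito_pct = 0` with a
#'   warning.
#' @param mito_prefix Feature-name prefix identifying mitochondrial genes
#'   when `mito_features` is `NULL` (default `"MT-"`).
#' @return A tibble with one row per cell: `cell`, `n_genes`, `n_umi`,
#'   `mito_pct`, and `zero_total` flagging cells without any count
#'   (their `mito_pct` is 0 by convention).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1))
#' qc_metrics(sim$counts)
#' @export
qc_metrics <- function(counts, mito_features = NULL, mito_prefix = "MT-") {
  assert_count_matrix(counts)
  if (is.null(mito_features)) {
    mito_features <- grep(paste0("^", mito_prefix), rownames(counts),
                          value = TRUE)
  } else {
    mito_features <- intersect(mito_features, rownames(counts))
  }
  if (length(mito_features) == 0L) {
    warn("no mitochondrial features found; mito_pct set to 0 for all cells")
  }
  n_umi <- colSums(counts)
  n_genes <- colSums(counts > 0)
  mito <- if (length(mito_features) > 0L) {
    colSums(counts[mito_features, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  zero <- n_umi == 0
  mito_pct <- ifelse(zero, 0, 100 * mito / pmax(n_umi, 1))
  tibble(
    cell = colnames(counts),
    n_genes = as.integer(n_genes),
    n_umi = as.numeric(n_umi),
    mito_pct = as.numeric(mito_pct),
    zero_total = zero
  )
}

#' Quality-control thresholds
#'
#' Removal is strict on every boundary: a cell is discarded when it has
#' fewer than `min_genes` or more than `max_genes` detected genes, fewer
#' than `min_umi` or more than `max_umi` total UMIs, or a mitochondrial
#' percentage above `max_mito_pct`. Cells sitting exactly on a boundary
#' are kept.
#'
#' @param min_genes,max_genes Detected-gene bounds (defaults 200 / 8000).
#' @param min_umi,max_umi Total-UMI bounds (defaults 1000 / 50000).
#' @param max_mito_pct Mitochondrial-percentage ceiling (default 15).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 8000,
                          min_umi = 1000, max_umi = 50000,
                          max_mito_pct = 15) {
  if (!(min_genes < max_genes) || !(min_umi < max_umi)) {
    stop_config("lower QC bounds must be below upper bounds")
  }
  if (max_mito_pct < 0 || max_mito_pct > 100) {
    stop_config("`max_mito_pct` must lie in [0, 100]")
  }
  structure(
    list(min_genes = min_genes, max_genes = max_genes,
         min_umi = min_umi, max_umi = max_umi,
         max_mito_pct = max_mito_pct),
    class = "qc_thresholds"
  )
}

#' Apply quality-control filters to per-cell metrics
#'
#' @param metrics Tibble from [qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @return The `metrics` tibble with an added logical `keep` column:
#'   `TRUE` iff `n_genes` is within `[min_genes, max_genes]`, `n_umi`
#'   within `[min_umi, max_umi]`, and `mito_pct <= max_mito_pct`.
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1))
#' qc_metrics(sim$counts) |> filter_cells(qc_thresholds(min_umi = 100))
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  dplyr::mutate(
    metrics,
    keep = .data$n_genes >= thresholds$min_genes &
      .data$n_genes <= thresholds$max_genes &
      .data$n_umi >= thresholds$min_umi &
      .data$n_umi <= thresholds$max_umi &
      .data$mito_pct <= thresholds$max_mito_pct
  )
}
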