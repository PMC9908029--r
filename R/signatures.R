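#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to `scale` total UMIs and log1p-transformed:
#' `log1p(scale * x / cell_total)`. Zeros map to zeros, so sparsity is
#' preserved. Cells with zero total counts yield all-zero columns with a
#' warning.
#'
#' @param counts Genes x cells sparse count matrix with dimnames.
#' @param scale Library-size scale factor (default 10,000).
#' @return A `dgCMatrix` of log-normalized expression, same dimnames.
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1))
#' expr <- log_normalize(sim$counts)
#' range(expr)
#' @export
log_normalize <- function(counts, scale = 1e4) {
  assert_count_matrix(counts)
  if (scale <= 0) stop_input("`scale` must be > 0")
  x <- as(as(counts, "CsparseMatrix"), "dgCMatrix")
  totals <- colSums(x)
  if (any(totals == 0)) {
    warn("cells with zero total counts map to all-zero columns")
  }
  div <- pmax(totals, 1)
  # column index of every stored entry of the dgCMatrix
  j <- rep.int(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p(scale * x@x / div[j])
  x
}

#' Expression-bin-matched module score
#'
#' Scores each cell for a gene set as the mean log-normalized expression
#' of the signature genes minus the mean of expression-matched control
#' genes. All genes are binned by their mean expression across cells into
#' `n_bins` equal-size bins; for every signature gene, `n_ctrl` control
#' genes are sampled (seeded) from its bin — without replacement when the
#' bin is large enough, with replacement otherwise. A signature drawn at
#' random from the background therefore scores 0 in expectation.
#'
#' @param expr Genes x cells log-normalized matrix ([log_normalize()]).
#' @param genes Character vector of signature genes; genes absent from
#'   `expr` are dropped with a warning, and an empty overlap is an error.
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Seed for the control-gene draw (deterministic scores).
#' @return A tibble with one row per cell: `cell`, `score`.
#' @examples
#' sim <- simulate_counts(sim_config(seed = 3))
#' expr <- log_normalize(sim$counts)
#' module_score(expr, sim$marker_genes[[1]], seed = 1)
#' @export
module_score <- function(expr, genes, n_bins = 25, n_ctrl = 100, seed = 0L) {
  assert_count_matrix(expr, "expr")
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L) {
    stop_input("no signature gene is present in the expression matrix")
  }
  if (length(present) < length(genes)) {
    warn(sprintf("%d signature gene(s) absent from the matrix were dropped",
                 length(genes) - length(present)))
  }
  gene_means <- rowMeans(expr)
  # equal-occupancy bins on the rank of mean expression
  bin <- cut(rank(gene_means, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(expr)
  by_bin <- split(rownames(expr), bin)

  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- by_bin[[as.character(bin[[g]])]]
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl, replace = FALSE)
      } else {
        sample(pool, n_ctrl, replace = TRUE)
      }
    }), use.names = FALSE)
  })

  sig_mean <- colMeans(expr[present, , drop = FALSE])
  # control draws keep multiplicity: the control mean weights repeats
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  tibble(cell = colnames(expr), score = as.numeric(sig_mean - ctrl_mean))
}

#' Classify cells as high- or low-cycling
#'
#' A cell is `HIGH_CYCLING` when its S-phase score or its G2-M score is
#' strictly positive, and `LOW_CYCLING` otherwise; exact zeros fall to
#' `LOW_CYCLING` so the rule is a total partition.
#'
#' @param s_score,g2m_score Numeric vectors of per-cell module scores.
#' @return Character vector of `"HIGH_CYCLING"` / `"LOW_CYCLING"`.
#' @export
classify_cycling <- function(s_score, g2m_score) {
  if (any(!is.finite(s_score)) || any(!is.finite(g2m_score))) {
    stop_input("cycling scores must be finite")
  }
  ifelse(s_score > 0 | g2m_score > 0, "HIGH_CYCLING", "LOW_CYCLING")
}

#' Cell-cycle scoring and high/low-cycling labels
#'
#' Convenience wrapper: module scores for caller-supplied S-phase and
#' G2-M gene lists, then [classify_cycling()]. Default lists matching the
#' widely used human cell-cycle genes ship as editable text fixtures under
#' `inst/extdata/`.
#'
#' @inheritParams module_score
#' @param s_genes,g2m_genes Character vectors of S-phase / G2-M genes.
#' @return Tibble: `cell`, `s_score`, `g2m_score`, `label`.
#' @export
score_cell_cycle <- function(expr, s_genes, g2m_genes,
                             n_bins = 25, n_ctrl = 100, seed = 0L) {
  s <- module_score(expr, s_genes, n_bins, n_ctrl, seed)
  g <- module_score(expr, g2m_genes, n_bins, n_ctrl, seed + 1L)
  tibble(
    cell = s$cell,
    s_score = s$score,
    g2m_score = g$score,
    label = classify_cycling(s$score, g$score)
  )
}

#' Derive cluster marker genes with rank-sum tests
#'
#' Candidate markers for a cluster must be expressed in at least
#' `min_pct` of the cluster's cells and over-expressed with a log fold
#' change (difference of mean log-normalized expression) above
#' `lfc_threshold`; candidates are then tested with a two-sample Wilcoxon
#' rank-sum test and Bonferroni-corrected by the number of tests actually
#' performed. Only over-expressed genes are reported (`direction = +1`).
#'
#' In `"one_vs_rest"` mode each cluster is compared against all remaining
#' cells. In `"pairwise"` mode a gene is retained for a cluster only when
#' it passes the fold-change, expression-fraction and corrected-p
#' thresholds against *every* other cluster; the reported fold change is
#' the weakest pairwise one and the reported p-values the largest.
#'
#' @param expr Genes x cells log-normalized matrix.
#' @param labels Tibble with columns `cell` and `cluster` covering the
#'   columns of `expr` (>= 2 clusters, each with >= 3 cells).
#' @param min_pct Minimum expressing fraction in the cluster (default
#'   0.05).
#' @param lfc_threshold Log fold-change threshold on the scale of the
#'   data (default 0.25).
#' @param alpha Significance level on the Bonferroni-corrected p-value
#'   (default 0.05).
#' @param mode `"one_vs_rest"` or `"pairwise"`.
#' @return A tibble: `cluster`, `gene`, `log_fold_change`,
#'   `fraction_expressing_in_cluster`, `p_value`, `p_bonferroni`,
#'   `direction` (always `+1L`), sorted by cluster then decreasing fold
#'   change.
#' @export
find_markers <- function(expr, labels, min_pct = 0.05, lfc_threshold = 0.25,
                         alpha = 0.05, mode = c("one_vs_rest", "pairwise")) {
  mode <- match.arg(mode)
  assert_count_matrix(expr, "expr")
  if (!all(c("cell", "cluster") %in% names(labels))) {
    stop_input("`labels` needs columns `cell` and `cluster`")
  }
  labels <- labels[match(colnames(expr), labels$cell), ]
  if (anyNA(labels$cluster)) stop_input("`labels` must cover every cell of `expr`")
  cl <- as.character(labels$cluster)
  sizes <- table(cl)
  if (length(sizes) < 2L) stop_input("need at least 2 clusters")
  if (any(sizes < 3L)) stop_input("every cluster needs at least 3 cells")

  clusters <- names(sizes)
  idx <- split(seq_len(ncol(expr)), cl)
  means <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE]),
                  numeric(nrow(expr)))
  pcts <- vapply(idx, function(i) rowMeans(expr[, i, drop = FALSE] > 0),
                 numeric(nrow(expr)))

  rows <- list()
  n_tests <- 0L
  for (k in clusters) {
    others <- setdiff(clusters, k)
    if (mode == "one_vs_rest") {
      rest <- unlist(idx[others], use.names = FALSE)
      lfc <- means[, k] - rowMeans(expr[, rest, drop = FALSE])
      cand <- which(pcts[, k] >= min_pct & lfc > lfc_threshold)
      if (length(cand) == 0L) next
      p <- vapply(cand, function(g) {
        wilcox.test(expr[g, idx[[k]]], expr[g, rest], exact = FALSE)$p.value
      }, numeric(1))
      n_tests <- n_tests + length(p)
      rows[[k]] <- tibble(
        cluster = k, gene = rownames(expr)[cand],
        log_fold_change = unname(lfc[cand]),
        fraction_expressing_in_cluster = unname(pcts[cand, k]),
        p_value = unname(p)
      )
    } else {
      lfc_pair <- means[, k] - means[, others, drop = FALSE]
      cand <- which(pcts[, k] >= min_pct &
                      apply(lfc_pair > lfc_threshold, 1L, all))
      if (length(cand) == 0L) next
      pmat <- vapply(others, function(j) {
        vapply(cand, function(g) {
          wilcox.test(expr[g, idx[[k]]], expr[g, idx[[j]]],
                      exact = FALSE)$p.value
        }, numeric(1))
      }, numeric(length(cand)))
      pmat <- matrix(pmat, nrow = length(cand))
      n_tests <- n_tests + length(pmat)
      rows[[k]] <- tibble(
        cluster = k, gene = rownames(expr)[cand],
        log_fold_change = apply(lfc_pair[cand, , drop = FALSE], 1L, min),
        fraction_expressing_in_cluster = unname(pcts[cand, k]),
        p_value = apply(pmat, 1L, max)
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(
      cluster = character(), gene = character(),
      log_fold_change = numeric(),
      fraction_expressing_in_cluster = numeric(),
      p_value = numeric(), p_bonferroni = numeric(), direction = integer()
    ))
  }
  out <- dplyr::bind_rows(rows)
  # Bonferroni denominator = number of p-values actually computed
  out$p_bonferroni <- pmin(1, out$p_value * n_tests)
  out <- out[out$p_bonferroni < alpha, , drop = FALSE]
  out$direction <- 1L
  dplyr::arrange(out, .data$cluster, dplyr::desc(.data$log_fold_change))
}

#' Default cell-cycle gene lists
#'
#' Reads the editable S-phase and G2-M gene lists shipped with the
#' package (one symbol per line).
#'
#' @return Named list with character vectors `s` and `g2m`.
#' @export
default_cell_cycle_genes <- function() {
  ext <- system.file("extdata", package = "myostate")
  list(
    s = readLines(file.path(ext, "s_phase_genes.txt")),
    g2m = readLines(file.path(ext, "g2m_phase_genes.txt"))
  )
}
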