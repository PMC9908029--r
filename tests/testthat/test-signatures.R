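test_that("log-normalization matches hand evaluation and is depth-invariant", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(10, 90),
                            dims = c(3, 2),
                            dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  expect_warning(expr <- log_normalize(m, scale = 1e4), "zero total")
  # count 10 in a 100-UMI cell at scale 10,000 -> log1p(1000)
  expect_equal(expr["g1", "c1"], log1p(1000))
  expect_equal(expr["g3", "c1"], 0)
  expect_true(all(expr[, "c2"] == 0))
  # doubling all counts of a cell leaves its normalized column unchanged
  expect_warning(doubled <- log_normalize(m * 2, scale = 1e4))
  expect_equal(as.numeric(expr[, "c1"]), as.numeric(doubled[, "c1"]))
})

test_that("module score reduces to expr minus bin mean for one gene", {
  sim <- simulate_counts(sim_config(seed = 41, n_genes = 100L,
                                    n_cells_per_state = c(A = 50L, B = 50L)))
  expr <- log_normalize(sim$counts)
  gene_means <- Matrix::rowMeans(expr)
  bin <- cut(rank(gene_means, ties.method = "first"), breaks = 4,
             labels = FALSE)
  g <- rownames(expr)[1]
  pool <- rownames(expr)[bin == bin[1]]
  sc <- module_score(expr, g, n_bins = 4, n_ctrl = length(pool), seed = 1)
  expected <- as.numeric(expr[g, ]) -
    Matrix::colMeans(expr[pool, , drop = FALSE])
  expect_equal(sc$score, unname(expected))
})

test_that("module score equals an independent re-derivation (same seed)", {
  sim <- simulate_counts(sim_config(seed = 42))
  expr <- log_normalize(sim$counts)
  genes <- sim$marker_genes[[1]]
  sc <- module_score(expr, genes, n_bins = 25, n_ctrl = 30, seed = 7)
  # independent re-derivation of binning and seeded control sampling
  gene_means <- Matrix::rowMeans(expr)
  bin <- cut(rank(gene_means, ties.method = "first"), breaks = 25,
             labels = FALSE)
  ctrl <- withr::with_seed(7L, unlist(lapply(genes, function(g) {
    pool <- rownames(expr)[bin == bin[match(g, rownames(expr))]]
    sample(pool, 30, replace = length(pool) < 30)
  })))
  expected <- Matrix::colMeans(expr[genes, ]) -
    Matrix::colMeans(expr[ctrl, ])
  expect_equal(sc$score, unname(as.numeric(expected)))
})

test_that("a null signature scores near zero and planted markers separate states", {
  cfg <- sim_config(seed = 43,
                    n_cells_per_state = c(A = 334L, B = 333L, C = 333L))
  sim <- simulate_counts(cfg)
  expr <- log_normalize(sim$counts)
  marker_genes <- unlist(sim$marker_genes)
  background <- setdiff(rownames(expr), c(marker_genes,
                                          grep("^MT-", rownames(expr),
                                               value = TRUE)))
  null_sig <- withr::with_seed(1, sample(background, 30))
  null_score <- module_score(expr, null_sig, seed = 2)
  expect_lt(abs(mean(null_score$score)), 0.05)

  sc <- module_score(expr, sim$marker_genes[["A"]], seed = 3)
  by_state <- tapply(sc$score, sim$truth$state, mean)
  expect_true(all(by_state[["A"]] > by_state[c("B", "C")]))
})

test_that("module score warns on absent genes and errors on empty overlap", {
  sim <- simulate_counts(sim_config(seed = 44, n_genes = 100L,
                                    n_cells_per_state = c(A = 30L, B = 30L)))
  expr <- log_normalize(sim$counts)
  expect_warning(module_score(expr, c("gene0001", "nope"), seed = 1),
                 "dropped")
  expect_error(module_score(expr, "nope", seed = 1),
               class = "myostate_input_error")
})

test_that("cycling classification is a strict-positive total partition", {
  expect_identical(classify_cycling(0.2, -0.1), "HIGH_CYCLING")
  expect_identical(classify_cycling(-0.1, -0.2), "LOW_CYCLING")
  expect_identical(classify_cycling(0, 0), "LOW_CYCLING")
  s <- withr::with_seed(5, rnorm(200))
  g <- withr::with_seed(6, rnorm(200))
  lab <- classify_cycling(s, g)
  expect_true(all(lab %in% c("HIGH_CYCLING", "LOW_CYCLING")))
  expect_identical(lab == "HIGH_CYCLING", s > 0 | g > 0)
  expect_error(classify_cycling(NA_real_, 1), class = "myostate_input_error")
})

test_that("marker derivation applies the fraction, fold-change and Bonferroni rules", {
  cfg <- sim_config(seed = 45, marker_log2fc = 2,
                    n_cells_per_state = c(A = 100L, B = 100L))
  sim <- simulate_counts(cfg)
  expr <- log_normalize(sim$counts)
  labels <- tibble::tibble(cell = sim$truth$cell, cluster = sim$truth$state)
  mk <- find_markers(expr, labels)
  # planted markers are recovered as over-expressed genes of their state
  expect_true(all(sim$marker_genes[["A"]] %in% mk$gene[mk$cluster == "A"]))
  expect_true(all(mk$log_fold_change > 0.25))
  expect_true(all(mk$p_bonferroni < 0.05))
  expect_true(all(mk$direction == 1L))

  # a gene expressed in <5% of the cluster is excluded whatever its level
  expr2 <- expr
  hi <- which(labels$cluster == "A")[1:4]  # 4% of cluster A
  expr2["gene0099", ] <- 0
  expr2["gene0099", hi] <- 10
  mk2 <- find_markers(expr2, labels)
  expect_false("gene0099" %in% mk2$gene[mk2$cluster == "A"])
})

test_that("marker derivation is stable under cell permutation and monotone in alpha", {
  cfg <- sim_config(seed = 46, n_cells_per_state = c(A = 60L, B = 60L))
  sim <- simulate_counts(cfg)
  expr <- log_normalize(sim$counts)
  labels <- tibble::tibble(cell = sim$truth$cell, cluster = sim$truth$state)
  mk <- find_markers(expr, labels)
  perm <- withr::with_seed(2, sample(ncol(expr)))
  mk_perm <- find_markers(expr[, perm], labels)
  expect_equal(mk, mk_perm)
  mk_strict <- find_markers(expr, labels, alpha = 0.001)
  expect_true(all(paste(mk_strict$cluster, mk_strict$gene) %in%
                    paste(mk$cluster, mk$gene)))
})

test_that("null clusters rarely yield any Bonferroni-passing marker", {
  n_bad <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed + 100L, marker_log2fc = 0, n_genes = 500L,
                      n_cells_per_state = c(A = 50L, B = 50L))
    sim <- simulate_counts(cfg)
    expr <- log_normalize(sim$counts)
    labels <- tibble::tibble(cell = sim$truth$cell, cluster = sim$truth$state)
    mk <- find_markers(expr, labels)
    if (nrow(mk) > 1L) n_bad <- n_bad + 1L
  }
  expect_lte(n_bad, 2L)
})

test_that("pairwise mode only keeps genes beating every other cluster", {
  cfg <- sim_config(seed = 47, marker_log2fc = 2,
                    n_cells_per_state = c(A = 80L, B = 80L, C = 80L))
  sim <- simulate_counts(cfg)
  expr <- log_normalize(sim$counts)
  labels <- tibble::tibble(cell = sim$truth$cell, cluster = sim$truth$state)
  mk <- find_markers(expr, labels, mode = "pairwise")
  # pairwise Bonferroni is stricter than one-vs-rest: expect most, not all,
  # planted markers at n = 80 cells per state
  expect_gte(mean(sim$marker_genes[["B"]] %in% mk$gene[mk$cluster == "B"]),
             0.9)
  # pairwise retention is at least as strict as one-vs-rest on planted data
  expect_true(all(mk$log_fold_change > 0.25))
  expect_true(all(mk$p_bonferroni < 0.05))
})

test_that("cell-cycle scoring wraps module scores into labels", {
  cfg <- sim_config(seed = 48, n_genes = 300L,
                    n_cells_per_state = c(A = 100L, B = 100L))
  sim <- simulate_counts(cfg)
  expr <- log_normalize(sim$counts)
  cc <- score_cell_cycle(expr, s_genes = sim$marker_genes[["A"]],
                         g2m_genes = sim$marker_genes[["B"]], seed = 1)
  expect_identical(nrow(cc), ncol(expr))
  expect_identical(cc$label, classify_cycling(cc$s_score, cc$g2m_score))
  lists <- default_cell_cycle_genes()
  expect_gt(length(lists$s), 30)
  expect_gt(length(lists$g2m), 40)
})
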