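# shared builders for synthetic fixtures; everything is generated in code

# one well-composition row on the 0-100 percent scale
comp_row <- function(q = 0, cm = 0, cp = 0, com = 0, d = 0,
                     plate = "P1", well = "A1", compound = "x", dose = 1,
                     n = 100L) {
  tibble::tibble(
    plate = plate, well = well, compound = compound, dose_um = dose,
    n_nuclei = n,
    pct_quiescent_musc = q, pct_cycling_musc = cm,
    pct_cycling_progenitor = cp, pct_committed = com,
    pct_differentiated = d,
    low_confidence = n < 20L
  )
}

# plate layout row with a named composition vector (fractions summing to 1)
layout_row <- function(well, compound, comp, dose = 1, n_cells = 2000L,
                       plate = "P1", unstained = FALSE) {
  tibble::tibble(
    plate = plate, well = well, compound = compound, dose_um = dose,
    n_cells = as.integer(n_cells), unstained = unstained,
    p_quiescent_musc = comp[1], p_cycling_musc = comp[2],
    p_cycling_progenitor = comp[3], p_committed = comp[4],
    p_differentiated = comp[5]
  )
}

unstained_row <- function(well = "H12", n_cells = 500L, plate = "P1") {
  layout_row(well, "UNSTAINED", rep(0, 5), dose = 0, n_cells = n_cells,
             plate = plate, unstained = TRUE)
}

# screen layout: null compounds share the control composition; planted
# differentiating / dedifferentiating compounds get shifted compositions
control_composition <- function() c(0.15, 0.15, 0.40, 0.20, 0.10)
diff_composition <- function() c(0.05, 0.05, 0.10, 0.45, 0.35)
dediff_composition <- function() c(0.35, 0.35, 0.15, 0.10, 0.05)

make_screen_layout <- function(n_compounds = 96L, n_diff = 5L, n_dediff = 5L,
                               n_cells = 2000L, plate = "P1") {
  comps <- sprintf("cmp%03d", seq_len(n_compounds))
  kind <- rep("null", n_compounds)
  kind[seq_len(n_diff)] <- "diff"
  kind[n_diff + seq_len(n_dediff)] <- "dediff"
  rows <- lapply(seq_len(n_compounds), function(i) {
    comp <- switch(kind[i],
                   diff = diff_composition(),
                   dediff = dediff_composition(),
                   control_composition())
    layout_row(sprintf("W%03d", i), comps[i], comp, n_cells = n_cells,
               plate = plate)
  })
  layout <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    layout_row("CTRL", "DMSO", control_composition(), dose = 0,
               n_cells = n_cells, plate = plate),
    unstained_row(plate = plate)
  )
  list(layout = layout,
       planted_diff = comps[kind == "diff"],
       planted_dediff = comps[kind == "dediff"])
}

# brute-force QC oracle: per-cell loop applying the three printed rules
qc_oracle_keep <- function(metrics, th) {
  vapply(seq_len(nrow(metrics)), function(i) {
    g <- metrics$n_genes[i]; u <- metrics$n_umi[i]; m <- metrics$mito_pct[i]
    !(g < th$min_genes || g > th$max_genes ||
        u < th$min_umi || u > th$max_umi ||
        m > th$max_mito_pct)
  }, logical(1))
}

# brute-force group-and-count composition oracle
compose_oracle <- function(cells) {
  keys <- unique(cells[, c("plate", "well")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- cells[cells$plate == keys$plate[i] & cells$well == keys$well[i], ]
    pct <- vapply(MYO_STATES_TEST, function(s) {
      100 * sum(sub$state == s) / nrow(sub)
    }, numeric(1), USE.NAMES = FALSE)
    tibble::tibble(plate = keys$plate[i], well = keys$well[i],
                   n_nuclei = nrow(sub), state = MYO_STATES_TEST, pct = pct)
  })
  dplyr::bind_rows(out)
}

MYO_STATES_TEST <- c("QUIESCENT_MUSC", "CYCLING_MUSC", "CYCLING_PROGENITOR",
                     "COMMITTED", "DIFFERENTIATED")

# simulate one null cohort and return the permutation p-value
null_cohort_pvalue <- function(seed, n_per_group = 24L, n_genes = 40L,
                               sig_size = 20L, B = 2000L) {
  cfg <- sim_config(seed = seed, cohort = cohort_config(
    n_live = n_per_group, n_dead = n_per_group, n_genes = n_genes
  ))
  cohort <- simulate_cohort(cfg)
  sig <- tibble::tibble(
    gene = sprintf("gene%04d", seq_len(sig_size)),
    direction = rep(c(1L, -1L), length.out = sig_size)
  )
  permutation_test(cohort, sig, B = B, seed = seed + 1L)$p_value
}
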