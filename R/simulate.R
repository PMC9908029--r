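#' Simulation configuration with planted ground truth
#'
#' Bundles every knob of the synthetic-data generators: negative-binomial
#' UMI counts with planted state markers and a controlled mitochondrial
#' fraction, hashtag-oligo (HTO) counts with one dominant hashtag per cell,
#' plate-based per-cell marker intensities with drug-shifted state
#' compositions, and a patient cohort with live/dead labels and an optional
#' planted signed signature.
#'
#' @param seed Integer seed; identical configurations (including `seed`)
#'   produce byte-identical outputs from every generator.
#' @param n_cells_per_state Named integer vector, cells to draw per
#'   transcriptional state (names are the state labels of the truth table).
#' @param n_genes Total number of genes, including mitochondrial genes.
#' @param n_marker_genes_per_state Marker genes planted per state.
#' @param marker_log2fc Planted marker effect, log2 units: a state's marker
#'   genes have negative-binomial mean `baseline_mean * 2^marker_log2fc`
#'   in that state and `baseline_mean` elsewhere.
#' @param baseline_mean Negative-binomial mean of non-marker expression.
#' @param dispersion Shared negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2` (`size = 1/dispersion`).
#' @param mito_fraction_range Length-2 interval in `[0, 1]`; each cell's
#'   mitochondrial UMI fraction is drawn uniformly from it and realised
#'   exactly by allocating that share of the cell's UMIs to the
#'   mitochondrial genes.
#' @param n_mito_genes Number of genes named `MT-1 ... MT-k` that receive
#'   the mitochondrial allocation.
#' @param n_hashtags Number of hashtag oligos (>= 2 for demultiplexing).
#' @param hto_signal_to_noise Ratio (> 0) of a cell's true-hashtag mean
#'   count to the background hashtag mean count.
#' @param hto_background_mean Background HTO mean count.
#' @param hto_dispersion Negative-binomial overdispersion of HTO counts
#'   (default 0.1): antibody-tag counts are much less overdispersed than
#'   RNA UMIs.
#' @param intensity_meanlog_neg,intensity_sep,intensity_sdlog Two-component
#'   lognormal imaging-intensity model: the negative (background) component
#'   has `meanlog = intensity_meanlog_neg`, the positive component
#'   `meanlog = intensity_meanlog_neg + intensity_sep`, both with
#'   `sdlog = intensity_sdlog`. `intensity_sep` controls how hard the
#'   gating problem is.
#' @param plate_layout Tibble describing one imaging plate: columns
#'   `plate`, `well`, `compound`, `dose_um`, `n_cells`, logical
#'   `unstained`, and the five composition columns
#'   `p_quiescent_musc, p_cycling_musc, p_cycling_progenitor, p_committed,
#'   p_differentiated` (each stained row must sum to 1).
#' @param cohort List as returned by [cohort_config()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()], [simulate_hto()], [simulate_plate()],
#'   [simulate_cohort()]
#' @export
sim_config <- function(seed = 1L,
                       n_cells_per_state = c(MUSC = 200L, PROGENITOR = 200L,
                                             DIFF = 200L),
                       n_genes = 1000L,
                       n_marker_genes_per_state = 20L,
                       marker_log2fc = 2,
                       baseline_mean = 0.5,
                       dispersion = 0.5,
                       mito_fraction_range = c(0.01, 0.10),
                       n_mito_genes = 10L,
                       n_hashtags = 4L,
                       hto_signal_to_noise = 20,
                       hto_background_mean = 10,
                       hto_dispersion = 0.1,
                       intensity_meanlog_neg = log(100),
                       intensity_sep = 2.5,
                       intensity_sdlog = 0.4,
                       plate_layout = NULL,
                       cohort = cohort_config()) {
  cfg <- list(
    seed = as.integer(seed),
    n_cells_per_state = n_cells_per_state,
    n_genes = as.integer(n_genes),
    n_marker_genes_per_state = as.integer(n_marker_genes_per_state),
    marker_log2fc = marker_log2fc,
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    mito_fraction_range = mito_fraction_range,
    n_mito_genes = as.integer(n_mito_genes),
    n_hashtags = as.integer(n_hashtags),
    hto_signal_to_noise = hto_signal_to_noise,
    hto_background_mean = hto_background_mean,
    hto_dispersion = hto_dispersion,
    intensity_meanlog_neg = intensity_meanlog_neg,
    intensity_sep = intensity_sep,
    intensity_sdlog = intensity_sdlog,
    plate_layout = plate_layout,
    cohort = cohort
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Cohort block of a simulation configuration
#'
#' @param n_live,n_dead Patients per vital-status group (each >= 2).
#' @param n_genes Genes in the cohort expression table.
#' @param baseline_log2 Mean log2 expression of every gene.
#' @param noise_sd Gaussian standard deviation of log2 expression.
#' @param planted_signature Optional signed signature (tibble with columns
#'   `gene` and `direction` in `{+1, -1}`); `NULL` simulates the null of
#'   no association between expression and survival.
#' @param effect_log2fc Planted shift: in deceased patients, up-genes of
#'   the planted signature are shifted by `+effect_log2fc`, down-genes by
#'   `-effect_log2fc`.
#' @return A list used as the `cohort` field of [sim_config()].
#' @export
cohort_config <- function(n_live = 30L, n_dead = 30L, n_genes = 200L,
                          baseline_log2 = 5, noise_sd = 1,
                          planted_signature = NULL, effect_log2fc = 1) {
  list(
    n_live = as.integer(n_live), n_dead = as.integer(n_dead),
    n_genes = as.integer(n_genes), baseline_log2 = baseline_log2,
    noise_sd = noise_sd, planted_signature = planted_signature,
    effect_log2fc = effect_log2fc
  )
}

validate_sim_config <- function(cfg) {
  if (length(cfg$n_cells_per_state) < 1L || any(cfg$n_cells_per_state <= 0)) {
    stop_config("`n_cells_per_state` must be positive counts")
  }
  if (is.null(names(cfg$n_cells_per_state)) ||
      anyDuplicated(names(cfg$n_cells_per_state))) {
    stop_config("`n_cells_per_state` must carry unique state names")
  }
  if (cfg$n_genes <= 0L || cfg$n_mito_genes < 0L) {
    stop_config("gene counts must be positive")
  }
  n_marker_total <- cfg$n_marker_genes_per_state * length(cfg$n_cells_per_state)
  if (n_marker_total + cfg$n_mito_genes > cfg$n_genes) {
    stop_config("marker and mitochondrial genes exceed `n_genes`")
  }
  if (cfg$baseline_mean <= 0 || cfg$dispersion < 0) {
    stop_config("`baseline_mean` must be > 0 and `dispersion` >= 0")
  }
  rng <- cfg$mito_fraction_range
  if (length(rng) != 2L || any(rng < 0) || any(rng >= 1) || rng[1] > rng[2]) {
    stop_config("`mito_fraction_range` must be an interval inside [0, 1)")
  }
  if (cfg$hto_signal_to_noise <= 0 || cfg$hto_background_mean <= 0) {
    stop_config("HTO signal and background means must be positive")
  }
  if (!is.null(cfg$plate_layout)) validate_plate_layout(cfg$plate_layout)
  invisible(cfg)
}

composition_cols <- function() paste0("p_", tolower(MYO_STATES))

validate_plate_layout <- function(layout) {
  need <- c("plate", "well", "compound", "dose_um", "n_cells", "unstained",
            composition_cols())
  missing <- setdiff(need, names(layout))
  if (length(missing) > 0L) {
    stop_config(paste0("plate layout lacks column(s): ",
                       paste(missing, collapse = ", ")))
  }
  stained <- layout[!layout$unstained, , drop = FALSE]
  if (nrow(stained) > 0L) {
    sums <- rowSums(as.matrix(stained[, composition_cols()]))
    if (any(abs(sums - 1) > 1e-9)) {
      stop_config("stained-well composition vectors must sum to 1 (tol 1e-9)")
    }
  }
  invisible(layout)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a sparse UMI count matrix with planted states
#'
#' Draws genes x cells negative-binomial counts. Each state's marker genes
#' have their mean elevated `2^marker_log2fc`-fold in cells of that state;
#' a designated set of mitochondrial genes (`MT-*`) receives a per-cell
#' share of UMIs drawn uniformly from `mito_fraction_range`, so the
#' mitochondrial percentage of every cell is controlled exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a `dgCMatrix`, genes x cells, with
#'   feature rownames and barcode colnames) and `truth`, a tibble of
#'   `cell` and planted `state`.
#' @examples
#' sim <- simulate_counts(sim_config(seed = 7))
#' dim(sim$counts)
#' dplyr::count(sim$truth, state)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  states <- names(cfg$n_cells_per_state)
  n_cells <- sum(cfg$n_cells_per_state)
  n_mito <- cfg$n_mito_genes
  n_expr <- cfg$n_genes - n_mito

  genes <- c(sprintf("gene%04d", seq_len(n_expr)),
             if (n_mito > 0L) paste0("MT-", seq_len(n_mito)))
  cells <- sprintf("cell%05d", seq_len(n_cells))
  cell_state <- rep(states, times = cfg$n_cells_per_state)

  # per-state marker gene blocks at the top of the expressed genes
  marker_idx <- split(
    seq_len(cfg$n_marker_genes_per_state * length(states)),
    rep(states, each = cfg$n_marker_genes_per_state)
  )[states]

  mu <- matrix(cfg$baseline_mean, nrow = n_expr, ncol = n_cells)
  for (s in states) {
    mu[marker_idx[[s]], cell_state == s] <-
      cfg$baseline_mean * 2^cfg$marker_log2fc
  }
  counts <- matrix(rnb(length(mu), mu, cfg$dispersion),
                   nrow = n_expr, ncol = n_cells)

  if (n_mito > 0L) {
    frac <- runif(n_cells, cfg$mito_fraction_range[1], cfg$mito_fraction_range[2])
    tot <- colSums(counts)
    mito_tot <- as.integer(round(tot * frac / (1 - frac)))
    mito <- vapply(mito_tot, function(m) {
      if (m == 0L) integer(n_mito) else as.integer(rmultinom(1, m, rep(1, n_mito)))
    }, integer(n_mito))
    counts <- rbind(counts, matrix(mito, nrow = n_mito))
  }
  dimnames(counts) <- list(genes, cells)
  list(
    counts = as(as(counts, "CsparseMatrix"), "dgCMatrix"),
    truth = tibble(cell = cells, state = cell_state),
    marker_genes = lapply(marker_idx, function(i) genes[i])
  )
}

#' Simulate hashtag-oligo counts for a set of cells
#'
#' Each cell's true hashtag has negative-binomial mean
#' `hto_signal_to_noise * hto_background_mean`; all other hashtags have
#' the background mean. At a signal-to-noise ratio of 1 the matrix carries
#' no identity information and demultiplexing collapses to chance.
#'
#' @param config A [sim_config()] (needs `n_hashtags >= 2`).
#' @param truth_sample Tibble with columns `cell` (unique barcodes) and
#'   `hashtag` (values among the configured hashtag ids `HTO1..HTOk`, or
#'   integer indices).
#' @return A `dgCMatrix` of hashtags x cells counts.
#' @export
simulate_hto <- function(config, truth_sample) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_hashtags < 2L) stop_config("need at least 2 hashtags")
  if (!all(c("cell", "hashtag") %in% names(truth_sample))) {
    stop_input("`truth_sample` needs columns `cell` and `hashtag`")
  }
  if (anyDuplicated(truth_sample$cell)) {
    stop_input("duplicate cell barcodes in `truth_sample`")
  }
  tags <- paste0("HTO", seq_len(config$n_hashtags))
  ht <- truth_sample$hashtag
  if (is.numeric(ht)) ht <- tags[ht]
  if (anyNA(ht) || !all(ht %in% tags)) {
    stop_input("`truth_sample` refers to unknown cells or hashtags")
  }
  with_seed(config$seed + 1L, {
    n <- nrow(truth_sample)
    mu <- matrix(config$hto_background_mean, nrow = config$n_hashtags, ncol = n,
                 dimnames = list(tags, truth_sample$cell))
    mu[cbind(match(ht, tags), seq_len(n))] <-
      config$hto_background_mean * config$hto_signal_to_noise
    x <- matrix(rnb(length(mu), mu, config$hto_dispersion),
                nrow = config$n_hashtags, dimnames = dimnames(mu))
    as(as(x, "CsparseMatrix"), "dgCMatrix")
  })
}

# positivity design of the five myogenic states on the three MYOscopy markers
state_marker_design <- function() {
  tibble(
    state = MYO_STATES,
    myog = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    ki67 = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    myhc = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Simulate a per-cell imaging plate with planted state compositions
#'
#' Cells in each stained well are drawn from the well's true five-state
#' composition; myogenin, Ki-67 and MyHC intensities come from the
#' two-component lognormal model of [sim_config()] according to each
#' state's marker positivity pattern. Unstained wells draw every marker
#' from the negative component only and serve as the background reference
#' for [estimate_background()].
#'
#' @param config A [sim_config()] whose `plate_layout` is set.
#' @param require_unstained Error if the layout contains no unstained well
#'   (default `TRUE`: gating needs a background reference).
#' @return A list with `cells` (tibble: `plate, well, compound, dose_um,
#'   cell_id, int_myog, int_ki67, int_myhc`) and `truth` (tibble:
#'   `cell_id, state`; `NA` state for unstained cells).
#' @export
simulate_plate <- function(config, require_unstained = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$plate_layout
  if (is.null(layout)) stop_config("`plate_layout` is not set in the config")
  validate_plate_layout(layout)
  if (require_unstained && !any(layout$unstained)) {
    stop_config("plate layout has no unstained well")
  }
  design <- state_marker_design()
  with_seed(config$seed + 2L, {
    rows <- purrr::pmap(layout, function(plate, well, compound, dose_um,
                                         n_cells, unstained, ...) {
      comp <- c(...)[composition_cols()]
      if (unstained) {
        st <- rep(NA_character_, n_cells)
        pos <- matrix(FALSE, n_cells, 3)
      } else {
        st <- sample(MYO_STATES, n_cells, replace = TRUE, prob = comp)
        pos <- as.matrix(design[match(st, design$state), c("myog", "ki67", "myhc")])
      }
      meanlog <- config$intensity_meanlog_neg + config$intensity_sep * pos
      ints <- matrix(rlnorm(3L * n_cells, meanlog = meanlog,
                            sdlog = config$intensity_sdlog), ncol = 3)
      tibble(
        plate = plate, well = well, compound = compound, dose_um = dose_um,
        cell_id = paste0(plate, "_", well, "_", seq_len(n_cells)),
        int_myog = ints[, 1], int_ki67 = ints[, 2], int_myhc = ints[, 3],
        .state = st
      )
    })
    cells <- dplyr::bind_rows(rows)
    list(
      cells = dplyr::select(cells, -".state"),
      truth = tibble(cell_id = cells$cell_id, state = cells$.state)
    )
  })
}

#' Simulate a patient cohort with optional planted survival signature
#'
#' Gaussian log2 expression per gene; when a planted signed signature is
#' supplied, its up-genes are shifted by `+effect_log2fc` and its
#' down-genes by `-effect_log2fc` in deceased patients, so the signed
#' cohort statistic of [signature_statistic()] has expectation
#' `effect_log2fc`.
#'
#' @param config A [sim_config()] whose `cohort` block is set.
#' @return A tibble: `patient_id`, `status` (`"live"`/`"dead"`), then one
#'   column per gene with log2 expression.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$cohort
  if (cc$n_live < 2L || cc$n_dead < 2L) {
    stop_config("need at least 2 patients per vital-status group")
  }
  genes <- sprintf("gene%04d", seq_len(cc$n_genes))
  sig <- cc$planted_signature
  if (!is.null(sig) && !all(sig$gene %in% genes)) {
    stop_input("planted signature references genes absent from the cohort")
  }
  with_seed(config$seed + 3L, {
    n <- cc$n_live + cc$n_dead
    status <- rep(c("live", "dead"), c(cc$n_live, cc$n_dead))
    expr <- matrix(rnorm(n * cc$n_genes, mean = cc$baseline_log2,
                         sd = cc$noise_sd),
                   nrow = n, dimnames = list(NULL, genes))
    if (!is.null(sig)) {
      shift <- cc$effect_log2fc * sig$direction
      expr[status == "dead", sig$gene] <-
        expr[status == "dead", sig$gene] +
        rep(shift, each = cc$n_dead)
    }
    dplyr::bind_cols(
      tibble(patient_id = sprintf("pt%03d", seq_len(n)), status = status),
      as_tibble(expr)
    )
  })
}
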