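#' Centered log-ratio normalization of hashtag counts
#'
#' For every cell, `clr_h = log(x_h + pc) - mean_h log(x_h + pc)` across
#' hashtags. The CLR vector of each cell sums to zero by construction,
#' which makes the subsequent argmax assignment invariant to per-cell
#' sequencing depth.
#'
#' @param hto Hashtags x cells count matrix (>= 2 hashtags) with dimnames.
#' @param pseudocount Positive pseudocount added before the log
#'   (default 1).
#' @return A tibble with one row per cell: `cell` followed by one CLR
#'   column per hashtag, named `clr_<hashtag>`.
#' @examples
#' cfg <- sim_config(seed = 2, n_hashtags = 3)
#' truth <- tibble::tibble(cell = paste0("c", 1:5),
#'                         hashtag = c(1, 2, 3, 1, 2))
#' clr_normalize_hto(simulate_hto(cfg, truth))
#' @export
clr_normalize_hto <- function(hto, pseudocount = 1) {
  assert_count_matrix(hto, "hto")
  if (nrow(hto) < 2L) {
    stop_input("CLR needs at least 2 hashtags")
  }
  if (pseudocount <= 0) stop_input("`pseudocount` must be > 0")
  lx <- log(as.matrix(hto) + pseudocount)
  clr <- sweep(lx, 2L, colMeans(lx), "-")
  out <- as_tibble(base::t(clr), .name_repair = "minimal")
  names(out) <- paste0("clr_", rownames(hto))
  dplyr::bind_cols(tibble(cell = colnames(hto)), out)
}

#' Assign cells to samples by maximal hashtag signal
#'
#' Each cell is assigned the hashtag achieving the maximum CLR value.
#' When the top two CLR values are exactly tied or differ by less than
#' `min_margin`, the cell is labelled `"AMBIGUOUS"` and gets no sample id;
#' downstream exclusion is left to the caller.
#'
#' @param clr Tibble from [clr_normalize_hto()].
#' @param hashtag_to_sample Named character vector mapping every hashtag
#'   id to a sample id.
#' @param min_margin Minimum CLR lead of the top hashtag over the runner-up
#'   (default 0: only exact ties are ambiguous).
#' @return A tibble: `cell`, the `clr_*` columns, `assigned_hashtag`
#'   (`"AMBIGUOUS"` when undecided) and `sample_id` (`NA` when ambiguous).
#' @export
demux_hashtags <- function(clr, hashtag_to_sample, min_margin = 0) {
  clr_cols <- grep("^clr_", names(clr), value = TRUE)
  if (length(clr_cols) < 2L) stop_input("`clr` must carry >= 2 clr_* columns")
  tags <- sub("^clr_", "", clr_cols)
  missing <- setdiff(tags, names(hashtag_to_sample))
  if (length(missing) > 0L) {
    stop_input(paste0("`hashtag_to_sample` misses hashtag(s): ",
                      paste(missing, collapse = ", ")))
  }
  m <- as.matrix(clr[, clr_cols])
  top <- max.col(m, ties.method = "first")
  sorted <- apply(m, 1L, function(v) sort(v, decreasing = TRUE)[1:2])
  margin <- sorted[1, ] - sorted[2, ]
  ambiguous <- margin < min_margin | margin == 0
  assigned <- ifelse(ambiguous, "AMBIGUOUS", tags[top])
  dplyr::mutate(
    clr,
    assigned_hashtag = assigned,
    sample_id = ifelse(ambiguous, NA_character_,
                       unname(hashtag_to_sample[assigned]))
  )
}
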