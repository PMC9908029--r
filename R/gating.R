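#' Background intensity thresholds from an unstained control
#'
#' Every plate carries an unstained control well; the background threshold
#' of each marker is a high quantile (default the 99th percentile) of that
#' well's intensities. A cell is called positive for a marker downstream
#' when its intensity is strictly greater than the threshold.
#'
#' @param unstained Tibble of unstained-well cells with columns
#'   `int_myog`, `int_ki67`, `int_myhc` (at least 50 cells recommended;
#'   fewer triggers a warning, none is an error).
#' @param quantile Background quantile in (0, 1] (default 0.99;
#'   `quantile = 1` uses the unstained maximum).
#' @return Tibble: `marker`, `threshold`, `quantile_used`.
#' @export
estimate_background <- function(unstained, quantile = 0.99) {
  if (nrow(unstained) == 0L) stop_input("unstained table is empty")
  missing <- setdiff(MYO_MARKERS, names(unstained))
  if (length(missing) > 0L) {
    stop_input(paste0("unstained table lacks marker column(s): ",
                      paste(missing, collapse = ", ")))
  }
  if (quantile <= 0 || quantile > 1) stop_input("`quantile` must be in (0, 1]")
  if (nrow(unstained) < 50L) {
    warn("fewer than 50 unstained cells; background thresholds are noisy")
  }
  tibble(
    marker = sub("^int_", "", MYO_MARKERS),
    threshold = vapply(MYO_MARKERS, function(m) {
      unname(stats::quantile(unstained[[m]], probs = quantile))
    }, numeric(1), USE.NAMES = FALSE),
    quantile_used = quantile
  )
}

#' Gate cells into the five myogenic states
#'
#' Positivity is strict (`intensity > threshold`). MyHC-positive cells are
#' `DIFFERENTIATED` regardless of the other markers; the remaining cells
#' fall into the 2x2 on (myogenin, Ki-67): myogenin- Ki-67- quiescent
#' MuSC-like, myogenin- Ki-67+ cycling MuSC-like, myogenin+ Ki-67+ cycling
#' progenitors, myogenin+ Ki-67- noncycling committed progenitors. Every
#' cell receives exactly one label.
#'
#' @param cells Per-cell tibble with columns `int_myog`, `int_ki67`,
#'   `int_myhc`.
#' @param thresholds Tibble from [estimate_background()].
#' @return `cells` with an added `state` column (one of the five labels).
#' @export
gate_cells <- function(cells, thresholds) {
  missing <- setdiff(MYO_MARKERS, names(cells))
  if (length(missing) > 0L) {
    stop_input(paste0("cell table lacks marker column(s): ",
                      paste(missing, collapse = ", ")))
  }
  th <- setNames(thresholds$threshold, thresholds$marker)
  need <- c("myog", "ki67", "myhc")
  if (!all(need %in% names(th))) {
    stop_input("thresholds must cover markers myog, ki67, myhc")
  }
  myog <- cells$int_myog > th[["myog"]]
  ki67 <- cells$int_ki67 > th[["ki67"]]
  myhc <- cells$int_myhc > th[["myhc"]]
  state <- dplyr::case_when(
    myhc ~ "DIFFERENTIATED",
    myog & ki67 ~ "CYCLING_PROGENITOR",
    myog & !ki67 ~ "COMMITTED",
    !myog & ki67 ~ "CYCLING_MUSC",
    .default = "QUIESCENT_MUSC"
  )
  dplyr::mutate(cells, state = state)
}

#' Per-well five-state composition
#'
#' Aggregates gated cells into one row per well: nuclei count and the
#' percentage (0-100) of each of the five myogenic states. The five
#' percentages of a non-empty well sum to 100 exactly. Wells with fewer
#' than `min_cells` nuclei are flagged low-confidence.
#'
#' @param cells Gated cell tibble ([gate_cells()]) with columns `plate`,
#'   `well`, `compound`, `dose_um`, `state`.
#' @param min_cells Nuclei count below which a well is flagged
#'   (default 20).
#' @return Tibble: `plate`, `well`, `compound`, `dose_um`, `n_nuclei`,
#'   the five `pct_*` columns, and `low_confidence`.
#' @export
compose_wells <- function(cells, min_cells = 20L) {
  need <- c("plate", "well", "compound", "dose_um", "state")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0L) {
    stop_input(paste0("gated table lacks column(s): ",
                      paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(cells$state), MYO_STATES)
  if (length(bad) > 0L) {
    stop_input(paste0("unknown state label(s): ", paste(bad, collapse = ", ")))
  }
  comp <- cells |>
    dplyr::mutate(state = paste0("pct_", tolower(.data$state))) |>
    dplyr::count(.data$plate, .data$well, .data$compound, .data$dose_um,
                 .data$state) |>
    dplyr::group_by(.data$plate, .data$well, .data$compound, .data$dose_um) |>
    dplyr::mutate(n_nuclei = sum(.data$n),
                  pct = 100 * .data$n / .data$n_nuclei) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "state", values_from = "pct",
                       values_fill = 0)
  for (col in setdiff(pct_cols(), names(comp))) comp[[col]] <- 0
  comp |>
    dplyr::mutate(low_confidence = .data$n_nuclei < min_cells) |>
    dplyr::select(dplyr::all_of(c("plate", "well", "compound", "dose_um",
                                  "n_nuclei", pct_cols(), "low_confidence")))
}

#' Responder classification by differentiated fraction
#'
#' A sample responds to a differentiation-inducing treatment when its
#' percentage of differentiated (MyHC+) cells strictly exceeds the
#' threshold (default 10%); a sample exactly at the threshold is a
#' nonresponder.
#'
#' @param pct_differentiated Percentage of differentiated cells, 0-100.
#' @param threshold Percent threshold (default 10).
#' @return Character vector `"RESPONDER"` / `"NONRESPONDER"`.
#' @export
classify_responder <- function(pct_differentiated, threshold = 10) {
  if (any(pct_differentiated < 0 | pct_differentiated > 100, na.rm = TRUE)) {
    stop_input("`pct_differentiated` must lie in [0, 100]")
  }
  ifelse(pct_differentiated > threshold, "RESPONDER", "NONRESPONDER")
}
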