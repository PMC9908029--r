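# bracket terms of the two scores, on the 0-100 percent scale
diff_bracket <- function(comp) {
  comp$pct_committed + comp$pct_differentiated - comp$pct_cycling_progenitor
}
musc_bracket <- function(comp) {
  comp$pct_quiescent_musc + comp$pct_cycling_musc
}

avg_composition <- function(comp) {
  dplyr::summarise(comp, dplyr::across(dplyr::all_of(pct_cols()), mean))
}

#' Differentiating and dedifferentiating drug scores
#'
#' The differentiating score of a treated condition is
#' `(%committed + %differentiated - %cycling progenitors)` of the treated
#' wells minus the same bracket of the untreated control; the
#' dedifferentiating score is `(%quiescent MuSC-like + %cycling
#' MuSC-like)` treated minus control. Replicate wells are averaged at the
#' composition level before scoring, so a condition scored against itself
#' is exactly 0 and the scores are antisymmetric in their arguments.
#'
#' @param treated,control Well-composition tibbles ([compose_wells()]);
#'   multiple rows are averaged.
#' @return A single numeric score (percent points; the differentiating
#'   score lies in \[-200, 200\], the dedifferentiating score in
#'   \[-100, 100\]).
#' @examples
#' t1 <- tibble::tibble(pct_quiescent_musc = 0, pct_cycling_musc = 0,
#'   pct_cycling_progenitor = 10, pct_committed = 30, pct_differentiated = 20)
#' c1 <- tibble::tibble(pct_quiescent_musc = 0, pct_cycling_musc = 0,
#'   pct_cycling_progenitor = 40, pct_committed = 10, pct_differentiated = 5)
#' differentiating_score(t1, c1)  # 65
#' @export
differentiating_score <- function(treated, control) {
  check_composition(treated); check_composition(control)
  diff_bracket(avg_composition(treated)) - diff_bracket(avg_composition(control))
}

#' @rdname differentiating_score
#' @export
dedifferentiating_score <- function(treated, control) {
  check_composition(treated); check_composition(control)
  musc_bracket(avg_composition(treated)) - musc_bracket(avg_composition(control))
}

check_composition <- function(comp) {
  missing <- setdiff(pct_cols(), names(comp))
  if (length(missing) > 0L) {
    stop_input(paste0("composition lacks column(s): ",
                      paste(missing, collapse = ", ")))
  }
  if (nrow(comp) == 0L) stop_input("empty composition table")
  invisible(comp)
}

# MuSC fold change treated/control; +Inf when arising from a zero control
# with a positive treated fraction, NA when both are zero
musc_fold <- function(treated_musc, control_musc) {
  dplyr::case_when(
    control_musc > 0 ~ treated_musc / control_musc,
    treated_musc > 0 ~ Inf,
    .default = NA_real_
  )
}

#' Score a whole screen of well compositions
#'
#' Scores every compound x dose condition of a plate (or set of plates)
#' against the untreated control of its own plate, then averages across
#' plates. Hit calls are made at the reference dose: a differentiating hit
#' strictly increases `%committed + %differentiated` and strictly
#' decreases `%cycling progenitors` versus control; a dedifferentiating
#' hit raises the MuSC-like percentage (quiescent + cycling) by at least
#' `fold_threshold`-fold (1.5 by default, boundary included).
#'
#' @param compositions Well-composition tibble from [compose_wells()].
#' @param control_compound Compound id of the untreated control wells
#'   (default `"DMSO"`); every plate must contain it.
#' @param hit_dose Reference dose (same units as `dose_um`) at which hits
#'   are called (default 1, i.e. 1 uM). Other doses get `NA` hit flags.
#' @param fold_threshold Minimum MuSC fold change of a dedifferentiating
#'   hit (default 1.5).
#' @param margin Optional minimum effect (percent points) for the strict
#'   differentiating-hit inequalities (default 0).
#' @return A `screen_result` tibble, one row per compound x dose:
#'   `compound`, `dose_um`, `n_wells`, `s_diff`, `s_dediff`, `fold_musc`,
#'   `is_diff_hit`, `is_dediff_hit`. Control rows score exactly 0.
#' @export
screen_score <- function(compositions, control_compound = "DMSO",
                         hit_dose = 1, fold_threshold = 1.5, margin = 0) {
  check_composition(compositions)
  ctrl <- compositions |>
    dplyr::filter(.data$compound == control_compound) |>
    dplyr::group_by(.data$plate)
  if (dplyr::n_groups(ctrl) == 0L) {
    stop_input(paste0("no control wells for compound '", control_compound, "'"))
  }
  ctrl <- ctrl |>
    avg_composition() |>
    dplyr::ungroup()
  no_ctrl <- setdiff(unique(compositions$plate), ctrl$plate)
  if (length(no_ctrl) > 0L) {
    stop_input(paste0("plate(s) without control wells: ",
                      paste(no_ctrl, collapse = ", ")))
  }
  per_plate <- compositions |>
    dplyr::group_by(.data$plate, .data$compound, .data$dose_um) |>
    dplyr::summarise(n_wells = dplyr::n(),
                     dplyr::across(dplyr::all_of(pct_cols()), mean),
                     .groups = "drop") |>
    dplyr::left_join(ctrl, by = "plate", suffix = c("", "_ctrl"))

  res <- per_plate |>
    dplyr::mutate(
      s_diff = (.data$pct_committed + .data$pct_differentiated -
                  .data$pct_cycling_progenitor) -
        (.data$pct_committed_ctrl + .data$pct_differentiated_ctrl -
           .data$pct_cycling_progenitor_ctrl),
      s_dediff = (.data$pct_quiescent_musc + .data$pct_cycling_musc) -
        (.data$pct_quiescent_musc_ctrl + .data$pct_cycling_musc_ctrl),
      cd_treated = .data$pct_committed + .data$pct_differentiated,
      cd_ctrl = .data$pct_committed_ctrl + .data$pct_differentiated_ctrl,
      cp_treated = .data$pct_cycling_progenitor,
      cp_ctrl = .data$pct_cycling_progenitor_ctrl,
      musc_treated = .data$pct_quiescent_musc + .data$pct_cycling_musc,
      musc_ctrl = .data$pct_quiescent_musc_ctrl + .data$pct_cycling_musc_ctrl
    ) |>
    dplyr::group_by(.data$compound, .data$dose_um) |>
    dplyr::summarise(
      n_wells = sum(.data$n_wells),
      dplyr::across(dplyr::all_of(c("s_diff", "s_dediff", "cd_treated",
                                    "cd_ctrl", "cp_treated", "cp_ctrl",
                                    "musc_treated", "musc_ctrl")), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold_musc = musc_fold(.data$musc_treated, .data$musc_ctrl),
      at_ref = .data$dose_um == hit_dose &
        .data$compound != control_compound,
      is_diff_hit = dplyr::if_else(
        .data$at_ref,
        .data$cd_treated > .data$cd_ctrl + margin &
          .data$cp_treated < .data$cp_ctrl - margin,
        NA
      ),
      is_dediff_hit = dplyr::if_else(
        .data$at_ref,
        !is.na(.data$fold_musc) & .data$fold_musc >= fold_threshold,
        NA
      )
    ) |>
    dplyr::select(dplyr::all_of(c("compound", "dose_um", "n_wells", "s_diff",
                                  "s_dediff", "fold_musc", "is_diff_hit",
                                  "is_dediff_hit")))
  class(res) <- c("screen_result", class(res))
  res
}

#' Combined differentiating score of a combination screen
#'
#' Averages the differentiating scores of a compound at the four screened
#' doses and subtracts the score of the backbone treatment alone, so a
#' combination adding nothing over the backbone scores 0.
#'
#' @param dose_scores Numeric vector of differentiating scores at the four
#'   doses (10 uM, 1 uM, 100 nM, 10 nM).
#' @param backbone_score Differentiating score of the backbone compound
#'   alone (e.g. 50 nM trametinib).
#' @param allow_partial Accept fewer than four dose scores and average the
#'   ones present (default `FALSE`: missing doses are an error).
#' @return A single numeric combined score.
#' @examples
#' combined_differentiating_score(c(10, 20, 30, 40), backbone_score = 15)  # 10
#' @export
combined_differentiating_score <- function(dose_scores, backbone_score,
                                           allow_partial = FALSE) {
  if (length(backbone_score) != 1L || is.na(backbone_score)) {
    stop_input("a single backbone score is required")
  }
  dose_scores <- dose_scores[!is.na(dose_scores)]
  if (length(dose_scores) < 4L && !allow_partial) {
    stop_input("need differentiating scores at all four doses")
  }
  if (length(dose_scores) == 0L) stop_input("no dose scores supplied")
  mean(dose_scores) - backbone_score
}

#' Combined scores for every compound of a combination screen
#'
#' @param results A `screen_result` tibble ([screen_score()]) of the
#'   combination screen.
#' @param backbone_score Differentiating score of the backbone alone.
#' @param doses Doses averaged (default `c(10, 1, 0.1, 0.01)` uM).
#' @inheritParams combined_differentiating_score
#' @return Tibble: `compound`, `s_combined`.
#' @export
screen_combine <- function(results, backbone_score,
                           doses = c(10, 1, 0.1, 0.01),
                           allow_partial = FALSE) {
  results |>
    dplyr::filter(.data$dose_um %in% doses) |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      s_combined = combined_differentiating_score(
        .data$s_diff, backbone_score, allow_partial = allow_partial
      )
    )
}

#' Rank shared hits of two screens
#'
#' Intersects the hits of two screens (e.g. the same library run on two
#' patient-derived cultures) and ranks the shared compounds by the mean of
#' their two scores, descending; ties break lexicographically by compound
#' id so the ranking is deterministic.
#'
#' @param a,b `screen_result` tibbles restricted to comparable conditions.
#' @param score Column used for ranking: `"s_dediff"` or `"s_diff"`.
#' @param hit Column with the hit flag: `"is_dediff_hit"` or
#'   `"is_diff_hit"`.
#' @return Tibble of shared hits: `compound`, `score_a`, `score_b`,
#'   `mean_score`, `rank`. Empty when the hit sets are disjoint.
#' @export
rank_and_intersect <- function(a, b, score = c("s_dediff", "s_diff"),
                               hit = c("is_dediff_hit", "is_diff_hit")) {
  score <- match.arg(score)
  hit <- match.arg(hit)
  pick <- function(x, suffix) {
    x <- dplyr::filter(x, !is.na(.data[[hit]]) & .data[[hit]])
    out <- tibble(compound = x$compound)
    out[[paste0("score_", suffix)]] <- x[[score]]
    out
  }
  shared <- dplyr::inner_join(pick(a, "a"), pick(b, "b"), by = "compound")
  shared |>
    dplyr::mutate(mean_score = (.data$score_a + .data$score_b) / 2) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$compound) |>
    dplyr::mutate(rank = dplyr::row_number())
}
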