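#' Plot a scored screen
#'
#' Ranked bar chart of one of the two drug scores; hits at the reference
#' dose are highlighted.
#'
#' @param object A `screen_result` tibble from [screen_score()].
#' @param score `"s_diff"` or `"s_dediff"`.
#' @param dose_um Dose to display (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_result <- function(object, score = c("s_diff", "s_dediff"),
                                   dose_um = 1, ...) {
  score <- match.arg(score)
  hit_col <- if (score == "s_diff") "is_diff_hit" else "is_dediff_hit"
  df <- object |>
    dplyr::filter(.data$dose_um == !!dose_um) |>
    dplyr::mutate(
      hit = !is.na(.data[[hit_col]]) & .data[[hit_col]],
      compound = stats::reorder(.data$compound, .data[[score]])
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compound,
                                   y = .data[[score]],
                                   fill = .data$hit)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick"),
                               name = "hit") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = paste0(score, " (percent points vs control)")) +
    ggplot2::theme_minimal()
}

#' Stacked state-composition plot per well
#'
#' @param composition Tibble from [compose_wells()].
#' @return A ggplot: stacked bars of the five myogenic state percentages
#'   per well.
#' @export
plot_well_composition <- function(composition) {
  long <- composition |>
    tidyr::pivot_longer(dplyr::all_of(pct_cols()),
                        names_to = "state", values_to = "pct") |>
    dplyr::mutate(state = factor(sub("^pct_", "", .data$state),
                                 levels = tolower(MYO_STATES)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$well, y = .data$pct,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Spectral", name = "state") +
    ggplot2::labs(x = "well", y = "% of nuclei") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
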