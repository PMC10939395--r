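#' Plot a classification result
#'
#' Ranked +/- differential relative abundance per ASV, faceted by
#' experiment, with the bacterivore threshold drawn and CM calls
#' highlighted.
#'
#' @param object A `"cm_classification"` tibble.
#' @param threshold Threshold line to draw (percentage points).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cm_classification <- function(object, threshold = 0.1, ...) {
  d <- object %>%
    dplyr::group_by(.data$station, .data$date) %>%
    dplyr::arrange(dplyr::desc(.data$diff_pct), .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(call = dplyr::case_when(
      .data$is_cm ~ "active CM",
      .data$is_bacterivore ~ "bacterivore",
      TRUE ~ "no call"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$diff_pct,
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~ station + date, scales = "free_x") +
    ggplot2::labs(x = "ASV rank", y = "+BrdU - (-BrdU) difference (pp)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot CM abundance and proportion estimates over time
#'
#' @param object A `"cm_estimates"` tibble.
#' @param what `"abundance"` (cells per ml) or `"proportion"` (of
#'   phototrophs).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.cm_estimates <- function(object, what = c("abundance", "proportion"),
                                  ...) {
  what <- match.arg(what)
  cols <- if (what == "abundance") {
    c(potential = "potential_abundance", active = "active_abundance")
  } else {
    c(potential = "potential_proportion", active = "active_proportion")
  }
  d <- object %>%
    dplyr::select("station", "date", dplyr::all_of(unname(cols))) %>%
    tidyr::pivot_longer(-c("station", "date"), names_to = "kind",
                        values_to = "value") %>%
    dplyr::mutate(kind = dplyr::if_else(
      stringr::str_starts(.data$kind, "potential"), "potential", "active"))
  ylab <- if (what == "abundance") "CM abundance (cells per ml)" else
    "CM proportion of phototrophs"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date, y = .data$value,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$station, ncol = 1) +
    ggplot2::labs(x = NULL, y = ylab, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the environmental signal matrix
#'
#' Sign-only matrix of covariate signals per station and response, in the
#' blank/plus/minus convention: blank tiles are covariates with no signal
#' or pruned for collinearity.
#'
#' @param analysis A `"cm_env_analysis"` object.
#' @return A ggplot object.
#' @export
plot_signal_matrix <- function(analysis) {
  d <- tidy(analysis) %>%
    dplyr::mutate(label = dplyr::if_else(.data$sign == "", " ", .data$sign))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term,
                                  y = interaction(.data$station,
                                                  .data$response, sep = " / "),
                                  fill = .data$sign)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_manual(
      values = setNames(c("#b2df8a", "#fb9a99", "white", "white"),
                        c("+", "-", " ", "")),
      guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
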