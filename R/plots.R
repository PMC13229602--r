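#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an anchored scale
#'
#' Dot-and-interval chart of the anchored scores, items ordered by score,
#' anchors and concepts distinguished by shape/colour; the pinned 0 and 100
#' positions are marked. The standard visual for a panel run.
#'
#' @param object An `anchored_scale`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anchored_scale <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$label, levels = df$label[order(df$score)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$item,
                                   colour = .data$role)) +
    ggplot2::geom_vline(xintercept = c(0, 100), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Anchored score (0-100)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-item drift against the baseline
#'
#' @param object A `drift_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drift_report <- function(object, ...) {
  df <- object$items
  df$item <- factor(df$item_id, levels = df$item_id[order(df$baseline_score)])
  ggplot2::ggplot(df, ggplot2::aes(y = .data$item)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$baseline_ci_low, xmax = .data$baseline_ci_high),
      height = 0.25, colour = "grey60", na.rm = TRUE
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$baseline_score), shape = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$candidate_score,
                                     colour = .data$exceeds_band)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Anchored score (baseline interval, candidate filled)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
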