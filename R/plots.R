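#' Plot the per-level search of a weighted mining run
#'
#' Candidate weighted supports per level with the automatically generated
#' minimum-support threshold overlaid, so the pruning at each level is
#' visible at a glance.
#'
#' @param object A [mine_weighted()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.weighted_apriori <- function(object, ...) {
  cand <- dplyr::bind_rows(lapply(object$levels, function(l) {
    dplyr::mutate(dplyr::select(l$candidates, !"items"),
                  min_support = l$min_support,
                  survives = l$candidates$weighted_support >= l$min_support &
                    l$candidates$weighted_support > 0)
  }))
  ggplot2::ggplot(cand, ggplot2::aes(x = factor(.data$k),
                                     y = .data$weighted_support)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$survives),
                         width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min_support,
                                        ymax = .data$min_support),
                           linetype = 2, width = 0.5, colour = "black") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey60"),
                                 name = "survives") +
    ggplot2::labs(x = "itemset size k", y = "weighted support",
                  title = "Level-wise search with automatic minimum support",
                  subtitle = "dashed bar: the level's generated threshold") +
    ggplot2::theme_minimal()
}

#' Plot a method comparison curve
#'
#' Classic Apriori counts across the threshold grid as a curve, with the
#' weighted miner's single automatic operating point marked as a red dot at
#' its level-1 threshold.
#'
#' @param object A [compare_methods()] result.
#' @param metric `"patterns"` or `"rules"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mining_comparison <- function(object, metric = c("patterns", "rules"), ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "patterns") "n_patterns" else "n_rules"
  grid <- object$grid[object$grid$completed, , drop = FALSE]
  wrow <- object$methods[object$methods$method == "weighted", , drop = FALSE]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$min_support, y = .data[[ycol]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_point(data = tibble::tibble(min_support = object$effective_threshold,
                                              y = wrow[[ycol]]),
                        ggplot2::aes(x = .data$min_support, y = .data$y),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "minimum support", y = paste("number of", metric),
                  title = paste("Classic sweep vs. weighted operating point:", metric),
                  subtitle = "red dot: weighted miner with automatic per-level threshold") +
    ggplot2::theme_minimal()
}

#' Plot median rule confidence by itemset size for both methods
#'
#' @param comparison A [compare_methods()] result.
#' @return A ggplot.
#' @export
plot_median_confidence <- function(comparison) {
  stopifnot(inherits(comparison, "mining_comparison"))
  ggplot2::ggplot(comparison$median_confidence,
                  ggplot2::aes(x = factor(.data$union_size),
                               y = .data$median_confidence,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "itemset size", y = "median confidence",
                  title = "Rule quality by itemset size") +
    ggplot2::theme_minimal()
}
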