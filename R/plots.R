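#' Plot methods for evaluation curves, tuning grids and rankings
#'
#' `autoplot()` methods return ggplot objects: the ROC curve with the
#' chance diagonal, the precision-recall curve with the prevalence baseline
#' omitted (it depends on the data), and the tuning grid as mean out-of-bag
#' balanced accuracy against lambda (one line per sigma for WKLR).
#'
#' @param object A `litnet_roc`, `litnet_pr` or `litnet_tune` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name litnet-autoplot
NULL

#' @rdname litnet-autoplot
#' @export
autoplot.litnet_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", auc(object))) +
    ggplot2::theme_minimal()
}

#' @rdname litnet-autoplot
#' @export
autoplot.litnet_pr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall curve") +
    ggplot2::theme_minimal()
}

#' @rdname litnet-autoplot
#' @export
autoplot.litnet_tune <- function(object, ...) {
  grid <- object$grid
  p <- if (all(is.na(grid$sigma))) {
    ggplot2::ggplot(grid, ggplot2::aes(x = .data$lambda, y = .data$mean_score))
  } else {
    ggplot2::ggplot(grid, ggplot2::aes(x = .data$lambda, y = .data$mean_score,
                                       colour = factor(.data$sigma)))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lambda (log scale)",
                  y = "Mean out-of-bag balanced accuracy",
                  colour = "sigma",
                  title = "Bootstrap hyperparameter tuning") +
    ggplot2::theme_minimal()
}

#' Bar chart of a top-n centrality ranking
#'
#' @param ranked Tibble from [rank_top_n()].
#' @param benchmark Optional benchmark gene set; hits are highlighted.
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranked, benchmark = NULL) {
  stopifnot(all(c("gene", "score") %in% names(ranked)))
  df <- tibble::as_tibble(ranked)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  if (!is.null(benchmark)) {
    df$in_benchmark <- df$gene %in% as_seed_symbols(benchmark)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene,
                                          fill = .data$in_benchmark)) +
      ggplot2::labs(fill = "In benchmark")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene))
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "Centrality score", y = NULL) +
    ggplot2::theme_minimal()
}
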