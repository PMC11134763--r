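## ggplot2 autoplot methods for the package's result types.

#' Plot an explanation heatmap
#'
#' Query ions on the vertical axis, association rank on the horizontal;
#' cell darkness is proportional to relevance and each cell is annotated
#' with the reference m/z and the signed mass shift.
#'
#' @param object A [top_associations()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ms2sim_explanation
#' @export
autoplot.ms2sim_explanation <- function(object, ...) {
  df <- as.data.frame(object)
  df$query <- factor(sprintf("%.2f", df$query_mz),
                     levels = rev(sprintf("%.2f", unique(df$query_mz[order(df$rank)]))))
  df$lab <- sprintf("%.2f\n(%+.2f)", df$reference_mz, df$shift)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$assoc_rank), y = .data$query,
                                   fill = .data$relevance)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20") +
    ggplot2::labs(x = "association rank", y = "query ion m/z",
                  fill = "relevance") +
    ggplot2::theme_minimal()
}

#' Plot precision-recall curves of an evaluation
#'
#' @param object An [evaluate_pairs()] result.
#' @param what `"pr"` for precision-recall curves or `"mse"` for the
#'   per-bin squared-error summary.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ms2sim_eval
#' @export
autoplot.ms2sim_eval <- function(object, what = c("pr", "mse"), ...) {
  what <- match.arg(what)
  if (what == "pr") {
    df <- object$pr_curves
    df$cutoff <- sprintf("Tanimoto > %.1f", df$cutoff)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::facet_wrap(~cutoff) +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  } else {
    df <- object$per_bin[object$per_bin$n > 0L, ]
    df$bin_label <- sprintf("[%.1f, %.1f%s", df$lower, df$upper,
                            ifelse(df$upper >= 1, "]", ")"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_label)) +
      ggplot2::geom_linerange(ggplot2::aes(ymin = .data$se_q25, ymax = .data$se_q75)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$se_median), shape = 1) +
      ggplot2::geom_point(ggplot2::aes(y = .data$mse), color = "blue") +
      ggplot2::labs(x = "structural similarity bin",
                    y = "squared error (IQR, median; blue = MSE)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
}

#' Plot the training history of a fitted model
#'
#' @param object A trained `ms2sim_model` (with `history`).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ms2sim_model
#' @export
autoplot.ms2sim_model <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history")
  df <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                            names_to = "series", values_to = "mse")
  df <- df[!is.na(df$mse), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
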