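#' Plot per-fold cross-validation accuracy
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot: fold accuracies with the pooled accuracy as a line.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$accuracy, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "fold", y = "accuracy",
      title = sprintf("%s @ %s: pooled accuracy %.1f%%",
                      object$learner, object$rank, 100 * object$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the frequency intervals used by a rule model
#'
#' One horizontal segment per literal, grouped by concluded class; open
#' bounds are drawn at the data range.
#'
#' @param object A `rule_model`.
#' @param scale Display multiplier for frequencies (default `1e5`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rule_model <- function(object, scale = 1e5, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$kmer), , drop = FALSE]
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "default-only model"))
  }
  finite <- c(df$lo[is.finite(df$lo)], df$hi[is.finite(df$hi)])
  span <- if (length(finite)) range(finite) else c(0, 1)
  pad <- diff(span) * 0.1 + 1e-9
  df$lo_plot <- pmax(df$lo, span[1] - pad) * scale
  df$hi_plot <- pmin(df$hi, span[2] + pad) * scale
  ggplot2::ggplot(df, ggplot2::aes(y = .data$kmer)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo_plot,
                                       xend = .data$hi_plot,
                                       yend = .data$kmer,
                                       colour = .data$conclusion),
                          linewidth = 2) +
    ggplot2::labs(x = sprintf("frequency x %g", scale), y = "k-mer",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a per-rank accuracy report
#'
#' @param report Tibble from [per_rank_report()].
#' @return A ggplot: accuracy per rank and learner.
#' @export
plot_report <- function(report) {
  long <- tidyr::pivot_longer(
    report[, setdiff(names(report), c("avg", "sd"))],
    -"rank", names_to = "learner", values_to = "accuracy"
  )
  long$rank <- factor(long$rank, levels = TAX_RANKS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$accuracy,
                                     fill = .data$learner)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "taxonomic rank", y = "10-fold CV accuracy") +
    ggplot2::theme_minimal()
}
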