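#' Bar plot of modification-class frequencies
#'
#' @param profile Tibble from [modification_frequencies()].
#' @param samples Optional tibble `sample_id`, `condition` to colour by
#'   condition.
#' @return A ggplot object.
#' @export
plot_modification_frequencies <- function(profile, samples = NULL) {
  if (!is.null(samples)) {
    profile <- dplyr::left_join(profile,
                                samples[, c("sample_id", "condition")],
                                by = "sample_id")
    fill <- "condition"
  } else {
    fill <- "sample_id"
  }
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$class, y = 100 * .data$frequency,
                               fill = .data[[fill]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(x = NULL, y = "% of assigned reads",
                  title = "miRNA end-modification frequencies") +
    ggplot2::theme_minimal()
}

#' Bar plot of nontemplated U-/A-tail lengths
#'
#' @param tails Tibble from [tail_length_histogram()].
#' @param samples Optional tibble `sample_id`, `condition`.
#' @return A ggplot object.
#' @export
plot_tail_length_histogram <- function(tails, samples = NULL) {
  if (!is.null(samples)) {
    tails <- dplyr::left_join(tails, samples[, c("sample_id", "condition")],
                              by = "sample_id")
    fill <- "condition"
  } else {
    fill <- "sample_id"
  }
  ggplot2::ggplot(tails,
                  ggplot2::aes(x = factor(.data$tail_len),
                               y = .data$percent, fill = .data[[fill]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::facet_wrap(~tail_class) +
    ggplot2::labs(x = "tail length (nt)", y = "% of assigned reads",
                  title = "Nontemplated 3' tail lengths") +
    ggplot2::theme_minimal()
}

#' MA plot of a differential-expression result
#'
#' @param object An `isotail_de` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isotail_de
#' @export
autoplot.isotail_de <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tidy(object)
  df$significant <- !is.na(df$padj) & df$padj < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baseMean, y = .data$log2FC,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60",
                                            "TRUE" = "firebrick")) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change",
                  colour = paste0("padj < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a cross-experiment signature regression
#'
#' @param x An `isotail_sigreg` from [signature_regression()].
#' @return A ggplot object.
#' @export
plot_signature_regression <- function(x) {
  ggplot2::ggplot(x$points, ggplot2::aes(x = .data$log2FC_x,
                                         y = .data$log2FC_y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "log2FC (experiment X)", y = "log2FC (experiment Y)",
      title = sprintf("slope = %.2f, R² = %.2f, n = %d",
                      x$slope, x$r_squared, x$n)) +
    ggplot2::theme_minimal()
}
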