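# ggplot2 presentation of the pipeline's result objects. Wavenumber axes
# are drawn descending, as spectroscopists read spectra.

#' @export
autoplot.mir_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavenumber, y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression("Wavenumber (cm"^-1 * ")"),
                  y = "Absorbance (AU)",
                  title = object$sample_id,
                  subtitle = paste("stage:", object$stage)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_spectra_set <- function(object, by_class = !is.null(object$labels),
                                     ...) {
  d <- tidy(object)
  if (by_class) {
    d$outcome <- factor(rep(object$labels, each = length(object$grid)),
                        levels = c(0, 1), labels = c("alive", "deceased"))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavenumber,
                                         y = .data$absorbance,
                                         group = .data$sample_id,
                                         colour = .data$outcome))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavenumber,
                                         y = .data$absorbance,
                                         group = .data$sample_id))
  }
  p + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression("Wavenumber (cm"^-1 * ")"),
                  y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_selection <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$wavenumber, y = .data$count)) +
    ggplot2::geom_col(width = 2) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        colour = "red", linetype = "dashed") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression("Wavenumber (cm"^-1 * ")"),
                  y = sprintf("Selections over %d runs", object$config$n_runs),
                  subtitle = "dashed red line: retention threshold") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(object$runs,
                           cols = c("auroc", "cutoff", "sensitivity",
                                    "specificity"),
                           names_to = "metric", values_to = "value")
  d <- d[is.finite(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Monte Carlo CV over %d runs",
                                  object$summary$n_runs)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mir_model_comparison <- function(object, ...) {
  lab <- setNames(sprintf("%s (AUROC %.2f)", object$aurocs$model,
                          object$aurocs$auroc),
                  object$aurocs$model)
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$model)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_discrete(labels = lab) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Spearman marker network as an edge table
#'
#' Displays the correlation edges as a tile map: blue for positive, red for
#' negative correlations, matching the usual presentation of serum marker
#' networks.
#'
#' @param edges Edge tibble from [spearman_network()].
#' @return A ggplot object.
#' @export
plot_spearman_network <- function(edges) {
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$node_a, y = .data$node_b,
                                      fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
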