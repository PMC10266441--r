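#' Plot a closed-loop history
#'
#' Observed yields against experiment number, colored by phase, with the
#' best-so-far incumbent overlaid; when prior records are present their best
#' yield is shown as a dashed baseline.
#'
#' @param object History from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rxn_loop_history
#' @export
autoplot.rxn_loop_history <- function(object, ...) {
  cur <- current_records(object)
  trace <- best_so_far(object)
  pos <- seq_len(nrow(cur))
  df <- dplyr::mutate(cur, experiment = pos)
  tr <- dplyr::mutate(trace, experiment = pos)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$experiment, y = .data$score)) +
    ggplot2::geom_step(data = tr,
                       ggplot2::aes(y = .data$incumbent),
                       color = "grey40", linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(color = .data$phase), size = 1.6) +
    ggplot2::labs(x = "experiment", y = "yield (%)", color = "phase") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  old_max <- attr(trace, "old_max")
  if (!is.null(old_max) && is.finite(old_max)) {
    p <- p + ggplot2::geom_hline(yintercept = old_max, linetype = "dashed",
                                 color = "grey55")
  }
  p
}

#' Plot a descriptor PCA
#'
#' Item scores on the first two principal components.
#'
#' @param object A [descriptor_pca()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot descriptor_pca
#' @export
autoplot.descriptor_pca <- function(object, ...) {
  sc <- tidy(object)
  evr <- object$explained_variance_ratio
  p2 <- if ("PC2" %in% names(sc)) "PC2" else "PC1"
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data[[p2]],
                                   label = .data$item)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * evr[1L]),
      y = if (p2 == "PC2") sprintf("PC2 (%.0f%%)", 100 * evr[2L]) else p2) +
    ggplot2::theme_minimal()
}
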