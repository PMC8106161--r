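# ggplot2 visualisations for the package's result types.

#' Plot permutation null distributions
#'
#' Histograms of the permuted-response R2Y and Q2Y null distributions with
#' the observed values marked.
#'
#' @param object An `opls_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot opls_permutation
#' @export
autoplot.opls_permutation <- function(object, ...) {
  nulls <- tidy(object)
  obs <- tibble(
    statistic = c("R2Y", "Q2Y"),
    value = c(object$r2y, object$q2y)
  )
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = obs, ggplot2::aes(xintercept = .data$value),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = "null statistic", y = "count",
      title = sprintf(
        "Permutation validation (p(R2Y) = %.3g, p(Q2Y) = %.3g)",
        object$p_r2y, object$p_q2y
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PCoA ordination
#'
#' @param object A `pcoa_ord`.
#' @param axes Which two axes to draw (default first two).
#' @param colour Optional vector (e.g. group labels) used to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, axes = c(1, 2), colour = NULL, ...) {
  df <- tidy(object)
  ax <- paste0("Axis", axes)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]]
  )) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], 100 * object$prop_explained[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], 100 * object$prop_explained[axes[2]])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Correlation-circle plot of O2-PLS correlation loadings
#'
#' Features from both blocks plotted at their correlation-scaled loadings
#' on two joint components, inside the unit circle: features at ~0 degrees
#' from each other are positively associated, ~180 degrees negatively,
#' ~90 degrees uncorrelated.
#'
#' @param object A `correlation_loadings` object.
#' @param components Which two joint components to draw (default 1:2; with
#'   a 1-component model the second axis is zero).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_loadings
#' @export
autoplot.correlation_loadings <- function(object, components = c(1, 2), ...) {
  long <- tidy(object)
  n_comp <- max(long$component)
  get_axis <- function(k) {
    if (k <= n_comp) {
      long$corr[long$component == k]
    } else {
      rep(0, sum(long$component == 1))
    }
  }
  base <- long[long$component == 1, c("block", "feature_id")]
  base$x <- get_axis(components[1])
  base$y <- get_axis(components[2])
  circle <- tibble(
    x = cos(seq(0, 2 * pi, length.out = 200)),
    y = sin(seq(0, 2 * pi, length.out = 200))
  )
  ggplot2::ggplot(base, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circle, colour = "grey75") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$block)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("pcorr/qcorr, component %d", components[1]),
      y = sprintf("pcorr/qcorr, component %d", components[2])
    ) +
    ggplot2::theme_minimal()
}

#' Cross-block partial-Spearman heatmap
#'
#' Tile heatmap of covariate-adjusted partial Spearman correlations between
#' two feature sets; only pairs with raw `p < 0.05` are filled, and pairs
#' surviving FDR correction are outlined.
#'
#' @param object An `integration_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot integration_result
#' @export
autoplot.integration_result <- function(object, ...) {
  df <- object$heatmap
  df$fill <- ifelse(df$displayed, df$rho, NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$feature_x, y = .data$feature_y, fill = .data$fill
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(
      data = df[df$highlighted, , drop = FALSE],
      fill = NA, colour = "black", linewidth = 0.6
    ) +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red",
      limits = c(-1, 1), na.value = "grey95", name = "pSC rho"
    ) +
    ggplot2::labs(x = object$block_x, y = object$block_y) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' CV-error curves of an Mnet tuning run
#'
#' @param object An `mnet_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mnet_cv
#' @export
autoplot.mnet_cv <- function(object, ...) {
  df <- object$surface
  df$gamma_lab <- factor(sprintf("gamma = %g", df$gamma))
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$lambda), y = .data$mse,
    colour = factor(.data$alpha), group = factor(.data$alpha)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = log10(object$best$lambda),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~gamma_lab) +
    ggplot2::labs(
      x = "log10(lambda)", y = "CV mean squared error", colour = "alpha"
    ) +
    ggplot2::theme_minimal()
}
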