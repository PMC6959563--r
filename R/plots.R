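#' Plot a matrix-pencil decomposition
#'
#' Shows the observed series (points), the full model fit (mean plus all
#' retained components, dashed line), and each component offset by the mean
#' (solid lines), evaluated on a fine time grid.
#'
#' @param object A [pencil_decompose()] result.
#' @param x Observed values (optional; plotted as points when given).
#' @param timepoints Times of the observed values; defaults to the sampling
#'   grid of the decomposition.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pencil_decomposition
#' @export
autoplot.pencil_decomposition <- function(object, x = NULL,
                                          timepoints = (seq_len(object$n) - 1) * object$dt,
                                          ...) {
  grid <- seq(min(timepoints), max(timepoints), length.out = 400)
  fit <- tibble(
    time = grid,
    value = pencil_reconstruct(object, grid)
  )
  comp_df <- purrr::map_dfr(seq_len(nrow(object$components)), function(i) {
    tibble(
      time = grid,
      value = pencil_reconstruct(object, grid, include = i),
      component = sprintf(
        "T = %.1f h", object$components$period[i]
      )
    )
  })
  p <- ggplot2::ggplot(fit, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "expression") +
    ggplot2::theme_minimal()
  if (nrow(comp_df)) {
    p <- p + ggplot2::geom_line(
      data = comp_df,
      ggplot2::aes(colour = .data$component)
    )
  }
  if (!is.null(x)) {
    p <- p + ggplot2::geom_point(
      data = tibble(time = timepoints, value = x)
    )
  }
  p
}

#' Polar histogram of rhythm phases
#'
#' The classic dawn/dusk plot: peak times binned on the rhythm circle and
#' drawn as a rose diagram.
#'
#' @param phases Peak times in hours.
#' @param period Circle circumference in hours.
#' @param n_bins Number of bins.
#' @return A ggplot object.
#' @export
plot_phase_histogram <- function(phases, period = 12, n_bins = 12) {
  bins <- polar_histogram(phases, period = period, n_bins = n_bins)
  ggplot2::ggplot(bins, ggplot2::aes(
    x = (.data$lo + .data$hi) / 2, y = .data$count
  )) +
    ggplot2::geom_col(width = period / n_bins, fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(
      limits = c(0, period),
      breaks = seq(0, period - period / 4, by = period / 4)
    ) +
    ggplot2::labs(x = sprintf("peak time (h, %g-h circle)", period), y = "genes") +
    ggplot2::theme_minimal()
}

#' Plot a permutation FDR estimate
#'
#' Histogram of the per-permutation rhythmic-gene counts with the observed
#' count marked.
#'
#' @param object An [estimate_fdr()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fdr_estimate
#' @export
autoplot.fdr_estimate <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(
      x = "rhythmic genes per permutation",
      y = "permutations",
      title = sprintf(
        "%s: observed %d, FDR %.3g", object$criteria,
        object$observed, object$fdr
      )
    ) +
    ggplot2::theme_minimal()
}
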