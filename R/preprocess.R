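#' Average replicates of a long expression table
#'
#' Rhythm identification runs on the replicate-averaged series, so biological
#' duplicates are collapsed to their arithmetic mean at each timepoint before
#' decomposition.
#'
#' @param df Long expression tibble with columns `gene`, `time`, `rep`,
#'   `value` (a missing `rep` column is treated as a single replicate).
#' @return A tibble with columns `gene`, `time`, `value`, one row per gene
#'   and timepoint.
#' @export
average_replicates <- function(df) {
  check_expression_frame(df)
  if (!"rep" %in% names(df)) {
    return(as_tibble(df[c("gene", "time", "value")]))
  }
  n_rep <- dplyr::n_distinct(df$rep)
  counts <- df |>
    dplyr::count(.data$gene, .data$time, name = "n_obs")
  bad <- counts[counts$n_obs != n_rep, , drop = FALSE]
  if (nrow(bad)) {
    abort(sprintf(
      "gene %s is missing replicate value(s) at time %g",
      bad$gene[1], bad$time[1]
    ))
  }
  df |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("gene", "time")
    ) |>
    dplyr::arrange(.data$gene, .data$time)
}

#' Flag genes above a background expression threshold
#'
#' A gene is kept when its mean expression across all timepoints (and
#' replicates, if present) is strictly larger than the threshold. The default
#' 0.1 FPKM is the background level derived from genes known not to be
#' expressed in liver (see [background_threshold()]).
#'
#' @param df Long expression tibble (`gene`, `time`, `value`, optional
#'   `rep`).
#' @param threshold Expression level; genes with mean strictly above it pass.
#' @return A tibble with one row per gene: `gene`, `mean_value`, `expressed`
#'   (logical).
#' @export
expression_filter <- function(df, threshold = 0.1) {
  check_expression_frame(df)
  if (threshold < 0) abort("`threshold` must be non-negative")
  df |>
    dplyr::summarise(mean_value = mean(.data$value), .by = "gene") |>
    dplyr::mutate(expressed = .data$mean_value > threshold)
}

#' Background expression threshold from marker-gene means
#'
#' The background level is the mean expression of a panel of genes known not
#' to be expressed in the tissue, rounded up (ceiling) at the requested
#' decimal place; e.g. a 70-gene panel averaging 0.092 FPKM rounds up to 0.1.
#'
#' @param marker_means Numeric vector of per-gene mean expression values.
#' @param decimals Decimal place of the rounding grid (default 1).
#' @return The threshold, a single number.
#' @examples
#' background_threshold(c(0.07, 0.114)) # mean 0.092 -> 0.1
#' @export
background_threshold <- function(marker_means, decimals = 1) {
  if (!length(marker_means)) abort("`marker_means` must be non-empty")
  if (any(!is.finite(marker_means))) abort("`marker_means` must be finite")
  grid <- 10^decimals
  ceiling(mean(marker_means) * grid) / grid
}

#' Polynomial detrend with mean restoration
#'
#' Fits an ordinary-least-squares polynomial of the given order to the series
#' and subtracts it, then adds the raw mean back so the detrended series
#' keeps the original mean expression rather than centring at zero. Applied
#' to culture time courses whose baseline drifts after synchronization.
#'
#' @param x Numeric series, or a long expression tibble (`gene`, `time`,
#'   `value`) detrended gene by gene.
#' @param order Polynomial order (default 3).
#' @param ... Passed between methods.
#' @return Same shape as the input, detrended, with per-series mean equal to
#'   the raw mean.
#' @export
polynomial_detrend <- function(x, order = 3, ...) {
  UseMethod("polynomial_detrend")
}

#' @rdname polynomial_detrend
#' @param times Sample times (hours) for the numeric method; defaults to the
#'   sample index.
#' @export
polynomial_detrend.numeric <- function(x, order = 3, times = seq_along(x), ...) {
  detrend_series(x, times, order)
}

#' @rdname polynomial_detrend
#' @export
polynomial_detrend.data.frame <- function(x, order = 3, ...) {
  check_expression_frame(x)
  x |>
    dplyr::arrange(dplyr::across(dplyr::any_of(c("gene", "rep", "time")))) |>
    dplyr::mutate(
      value = detrend_series(.data$value, .data$time, order),
      .by = dplyr::any_of(c("gene", "rep"))
    )
}

detrend_series <- function(values, times, order) {
  order <- as.integer(order)
  if (order < 1) abort("`order` must be at least 1")
  if (order >= length(values) - 1) {
    abort(sprintf(
      "order %d would fit %d points (near-)perfectly and zero the series",
      order, length(values)
    ))
  }
  fit <- lm(values ~ stats::poly(times, order, raw = TRUE))
  unname(stats::residuals(fit)) + mean(values)
}

#' Log2 transform with a pseudocount
#'
#' Elementwise `log2(value + pseudocount)`; preparation step before
#' rank-based rhythm tests on detrended expression data.
#'
#' @param x Numeric vector or long expression tibble (`value` column
#'   transformed).
#' @param pseudocount Offset added before taking logs (default 0).
#' @return Same shape as the input.
#' @export
log2_prepare <- function(x, pseudocount = 0) {
  UseMethod("log2_prepare")
}

#' @rdname log2_prepare
#' @export
log2_prepare.numeric <- function(x, pseudocount = 0) {
  shifted <- x + pseudocount
  if (any(shifted <= 0)) {
    abort(sprintf(
      "log2 of non-positive value: %g + pseudocount %g <= 0",
      x[which(shifted <= 0)[1]], pseudocount
    ))
  }
  log2(shifted)
}

#' @rdname log2_prepare
#' @export
log2_prepare.data.frame <- function(x, pseudocount = 0) {
  check_expression_frame(x)
  dplyr::mutate(x, value = log2_prepare(.data$value, pseudocount))
}
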