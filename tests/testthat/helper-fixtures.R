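# Shared fixtures built in code.

hours48 <- seq(0, 46, by = 2)

# Forward model used as the independent oracle for recovery tests: evaluates
# mean + sum of damped cosines directly from (T, d, A, p).
oracle_series <- function(t, mean, period, decay, amplitude, peak) {
  v <- rep(mean, length(t))
  for (i in seq_along(period)) {
    phi <- (-2 * pi * peak[i] / period[i]) %% (2 * pi)
    v <- v + amplitude[i] * decay[i]^(t / period[i]) *
      cos(2 * pi * t / period[i] + phi)
  }
  v
}

# Random 1-3 component parameter draw satisfying the identifiability
# conditions (periods 6-30 h separated by >= 20%, decay 0.85-1.15,
# amplitudes within 100:1).
random_truth <- function(n_components = sample(1:3, 1)) {
  repeat {
    Tp <- sort(runif(n_components, 6, 30), decreasing = TRUE)
    if (n_components == 1 || all(Tp[-n_components] / Tp[-1] >= 1.2)) break
  }
  list(
    period = Tp,
    decay = runif(n_components, 0.85, 1.15),
    amplitude = 10^runif(n_components, -1, 1),
    peak = runif(n_components, 0, Tp)
  )
}

# Worst relative parameter error between a decomposition and a truth draw,
# matching components by period rank; peak error measured on the circle and
# scaled by the period.
recovery_error <- function(decomp_tbl, truth) {
  if (nrow(decomp_tbl) != length(truth$period)) {
    return(Inf)
  }
  o <- order(-decomp_tbl$period)
  ot <- order(-truth$period)
  dp <- abs(decomp_tbl$peak_time[o] - truth$peak[ot])
  dp <- pmin(dp, truth$period[ot] - dp)
  max(
    abs(decomp_tbl$period[o] - truth$period[ot]) / truth$period[ot],
    abs(decomp_tbl$decay[o] - truth$decay[ot]) / truth$decay[ot],
    abs(decomp_tbl$amplitude[o] - truth$amplitude[ot]) / truth$amplitude[ot],
    dp / truth$period[ot]
  )
}

# Small long-format expression tibble from a named list of value vectors.
make_expression <- function(series, times = hours48) {
  dplyr::bind_rows(lapply(names(series), function(g) {
    tibble::tibble(gene = g, time = times, value = series[[g]])
  }))
}

# Component-table row in decompose_genes() shape, for classify/compare tests.
component_row <- function(gene, mean, period, decay = 1, amplitude = 1,
                          peak_time = 0) {
  tibble::tibble(
    gene = gene, mean = mean, residual_rms = 0,
    n_components = length(period), component = seq_along(period),
    period = period, decay = decay, amplitude = amplitude,
    relative_amplitude = amplitude / mean, phase = 0, peak_time = peak_time
  )
}

# Exhaustive-permutation p-value for the two-group Watson-Wheeler test:
# enumerates every assignment of the pooled phases to groups of the given
# sizes and counts statistics at least as large as observed.
ww_permutation_p <- function(phase, group, period = 12) {
  n <- length(phase)
  na <- sum(group == unique(group)[1])
  w_obs <- unname(suppressWarnings(
    watson_wheeler_test(phase, group, period)
  )$statistic)
  splits <- utils::combn(n, na)
  ws <- apply(splits, 2, function(ix) {
    g <- rep("b", n)
    g[ix] <- "a"
    unname(suppressWarnings(watson_wheeler_test(phase, g, period))$statistic)
  })
  mean(ws >= w_obs - 1e-9)
}
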