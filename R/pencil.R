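#' Decompose a uniform time series into superimposed damped sinusoids
#'
#' The eigenvalue/matrix-pencil method models a uniformly sampled series as a
#' mean plus a sum of exponentially damped (or growing) sinusoids,
#' \deqn{x(t) = \mu + \sum_k A_k \, d_k^{t/T_k} \cos(2\pi t/T_k + \phi_k),}
#' and recovers each component's period \eqn{T}, per-cycle decay \eqn{d},
#' amplitude \eqn{A}, and phase \eqn{\phi} without pre-assigning a period
#' range. Internally the mean-adjusted series is arranged into a Hankel
#' matrix whose shifted pencil has the signal poles
#' \eqn{z_k = d_k^{\Delta t/T_k} e^{\pm 2\pi i \Delta t/T_k}} as generalized
#' eigenvalues; a rank-truncated singular value decomposition retains at most
#' `2k + 1` pole directions, complex-conjugate pole pairs become oscillatory
#' components, and their complex amplitudes are solved by least squares
#' against the pole basis.
#'
#' Real poles (the mean and any aperiodic trend) are never reported as
#' oscillations: a pole at unity is absorbed into the reported mean, other
#' real poles are left to the residual. Oscillations faster than the Nyquist
#' period `2 * dt` or slower than the observation span are not identifiable
#' and are discarded. Components are ranked by amplitude (ties broken by
#' longer period) and the top `k` returned.
#'
#' @param x Numeric vector, the series sampled at uniform intervals.
#' @param dt Sampling interval in hours.
#' @param k Maximum number of oscillatory components to report (default 3,
#'   the standard choice for 24 samples at 2-h resolution, which resolves up
#'   to the third harmonic of the circadian period).
#' @param pencil_fraction Pencil parameter as a fraction of the series
#'   length; the window `L = round(pencil_fraction * length(x))` is the usual
#'   bias/variance compromise at 0.5.
#' @param decay_per, Either `"cycle"` (default) to report decay as the
#'   per-cycle amplitude ratio (1 = sustained), or `"sample"` to report the
#'   per-sample pole magnitude `|z|`.
#' @return An object of class `pencil_decomposition`: a list with elements
#'   `mean`, `components` (a tibble with one row per component: `component`,
#'   `period`, `decay`, `amplitude`, `phase`, `peak_time`), `residual_rms`,
#'   `n`, `dt`, `L`, and `k`.
#' @examples
#' t <- seq(0, 46, by = 2)
#' x <- 5 + 3 * cos(2 * pi * t / 12)
#' pencil_decompose(x, dt = 2)
#' @seealso [pencil_reconstruct()], [remove_components()], [decompose_genes()]
#' @export
pencil_decompose <- function(x, dt, k = 3, pencil_fraction = 0.5,
                             decay_per = c("cycle", "sample")) {
  decay_per <- match.arg(decay_per)
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector")
  }
  n <- length(x)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be at least 1")
  if (n < 2 * (2 * k + 1)) {
    abort(sprintf(
      "series too short: %d samples cannot support k = %d components (need at least %d)",
      n, k, 2 * (2 * k + 1)
    ))
  }
  core <- pencil_core(x, dt, k, pencil_fraction)
  decay <- if (decay_per == "cycle") core$decay_cycle else core$decay_sample
  components <- tibble(
    component = seq_along(core$period),
    period = core$period,
    decay = decay,
    amplitude = core$amplitude,
    phase = core$phase,
    peak_time = core$peak_time
  )
  structure(
    list(
      mean = core$mu,
      components = components,
      residual_rms = core$residual_rms,
      n = n, dt = dt, L = core$L, k = k,
      decay_per = decay_per
    ),
    class = "pencil_decomposition"
  )
}

# Numeric core, shared with the fast per-matrix paths. Returns plain vectors.
pencil_core <- function(x, dt, k, pencil_fraction = 0.5) {
  n <- length(x)
  mu <- mean(x)
  y <- x - mu
  L <- as.integer(round(pencil_fraction * n))
  L <- max(min(L, n - 2L), 2L)
  span <- dt * n
  empty <- list(
    mu = mu, period = numeric(0), decay_cycle = numeric(0),
    decay_sample = numeric(0), amplitude = numeric(0), phase = numeric(0),
    peak_time = numeric(0), residual_rms = 0, L = L
  )
  if (all(abs(y) < 1e-12 * max(1, abs(mu)))) {
    return(empty)
  }
  # Hankel matrix of the mean-adjusted series, (n - L) x (L + 1)
  idx <- outer(seq_len(n - L), 0:L, `+`)
  Y <- matrix(y[idx], n - L, L + 1L)
  sv <- svd(Y, nu = 0)
  m <- min(2L * k + 1L, sum(sv$d > 1e-10 * sv$d[1]), L, n - L)
  if (m == 0L) {
    return(empty)
  }
  V <- sv$v[, seq_len(m), drop = FALSE]
  V1 <- V[seq_len(L), , drop = FALSE]
  V2 <- V[2:(L + 1L), , drop = FALSE]
  pole_map <- solve(crossprod(V1), crossprod(V1, V2))
  z <- eigen(pole_map, only.values = TRUE)$values
  # complex amplitudes: least squares of y on the pole basis z^t
  basis <- vapply(z, function(zz) zz^(0:(n - 1)), complex(n))
  gram <- Conj(t(basis)) %*% basis
  cc <- tryCatch(
    solve(gram, Conj(t(basis)) %*% y)[, 1],
    error = function(e) qr.solve(basis, as.complex(y))
  )
  fit <- Re(basis %*% cc)[, 1]
  residual_rms <- sqrt(mean((y - fit)^2))

  used <- rep(FALSE, m)
  mu_extra <- 0
  period <- decay_cycle <- decay_sample <- amplitude <- phase <- peak_time <- numeric(0)
  pair_tol <- 1e-8
  for (i in seq_len(m)) {
    if (used[i]) next
    if (abs(Im(z[i])) <= 1e-9 * max(Mod(z[i]), 1)) {
      used[i] <- TRUE
      # a unit pole is the constant left after mean adjustment
      if (abs(z[i] - 1) < 1e-6) mu_extra <- mu_extra + Re(cc[i])
      next
    }
    mate <- which(!used & abs(z - Conj(z[i])) < pair_tol * max(Mod(z[i]), 1))
    mate <- setdiff(mate, i)
    if (!length(mate)) {
      warn(sprintf("discarding unpaired complex pole %s", format(z[i])))
      used[i] <- TRUE
      next
    }
    j <- mate[1]
    used[c(i, j)] <- TRUE
    if (Im(z[i]) > 0) {
      zp <- z[i]
      cp <- cc[i]
    } else {
      zp <- z[j]
      cp <- cc[j]
    }
    w <- Arg(zp)
    # admissibility: slower than the span is trend, at/faster than Nyquist
    # is not identifiable
    if (w <= 2 * pi * dt / span || w >= pi * (1 - 1e-12)) next
    Tper <- 2 * pi * dt / w
    d_sample <- Mod(zp)
    d_cycle <- d_sample^(Tper / dt)
    A <- 2 * Mod(cp)
    phi <- Arg(cp) %% (2 * pi)
    p <- ((-phi) %% (2 * pi)) * Tper / (2 * pi)
    if (p >= Tper * (1 - 1e-12)) p <- 0
    period <- c(period, Tper)
    decay_cycle <- c(decay_cycle, d_cycle)
    decay_sample <- c(decay_sample, d_sample)
    amplitude <- c(amplitude, A)
    phase <- c(phase, phi)
    peak_time <- c(peak_time, p)
  }
  if (length(period)) {
    o <- order(-amplitude, -period)
    o <- o[seq_len(min(k, length(o)))]
    period <- period[o]
    decay_cycle <- decay_cycle[o]
    decay_sample <- decay_sample[o]
    amplitude <- amplitude[o]
    phase <- phase[o]
    peak_time <- peak_time[o]
  }
  list(
    mu = mu + mu_extra, period = period, decay_cycle = decay_cycle,
    decay_sample = decay_sample, amplitude = amplitude, phase = phase,
    peak_time = peak_time, residual_rms = residual_rms, L = L
  )
}

#' @export
print.pencil_decomposition <- function(x, ...) {
  cat(sprintf(
    "Matrix-pencil decomposition: %d samples at dt = %g h (L = %d, k = %d)\n",
    x$n, x$dt, x$L, x$k
  ))
  cat(sprintf("  mean %.6g, residual RMS %.6g\n", x$mean, x$residual_rms))
  if (nrow(x$components) == 0) {
    cat("  no oscillatory components\n")
  } else {
    print(x$components, ...)
  }
  invisible(x)
}

#' Tidy a matrix-pencil decomposition into its component table
#'
#' @param x A [pencil_decompose()] result.
#' @param ... Unused.
#' @return A tibble with one row per oscillatory component (`component`,
#'   `period`, `decay`, `amplitude`, `phase`, `peak_time`), ranked by
#'   amplitude.
#' @method tidy pencil_decomposition
#' @export
tidy.pencil_decomposition <- function(x, ...) {
  x$components
}

#' One-row summary of a matrix-pencil decomposition
#'
#' @param x A [pencil_decompose()] result.
#' @param ... Unused.
#' @return A one-row tibble: `mean`, `n_components`, `residual_rms`, `n`,
#'   `dt`, `L`, `k`.
#' @method glance pencil_decomposition
#' @export
glance.pencil_decomposition <- function(x, ...) {
  tibble(
    mean = x$mean,
    n_components = nrow(x$components),
    residual_rms = x$residual_rms,
    n = x$n, dt = x$dt, L = x$L, k = x$k
  )
}

#' Reconstruct a series from selected decomposition components
#'
#' Evaluates the decomposition's mean plus the selected damped sinusoids at
#' arbitrary times: `mu + sum A * d^(t/T) * cos(2 pi t/T + phi)`.
#'
#' @param decomposition A [pencil_decompose()] result.
#' @param timepoints Numeric vector of times (hours) at which to evaluate.
#' @param include Integer indices of the components to include (rows of the
#'   component table). Defaults to all components; `integer(0)` gives the
#'   constant mean.
#' @return Numeric vector of reconstructed values, one per timepoint.
#' @export
pencil_reconstruct <- function(decomposition, timepoints,
                               include = seq_len(nrow(decomposition$components))) {
  stopifnot(inherits(decomposition, "pencil_decomposition"))
  comp <- decomposition$components
  include <- as.integer(include)
  if (length(include) && (any(include < 1) || any(include > nrow(comp)))) {
    abort(sprintf(
      "unknown component index %d (decomposition has %d components)",
      include[which(include < 1 | include > nrow(comp))[1]], nrow(comp)
    ))
  }
  out <- rep(decomposition$mean, length(timepoints))
  for (i in include) {
    out <- out + eval_component(
      timepoints, comp$period[i], comp$decay[i], comp$amplitude[i], comp$phase[i]
    )
  }
  out
}

# One damped cosine A * d^(t/T) * cos(2 pi t/T + phi)
eval_component <- function(t, period, decay, amplitude, phase) {
  amplitude * decay^(t / period) * cos(2 * pi * t / period + phase)
}

#' Remove components in a period window from a series
#'
#' Subtracts the reconstruction (without the mean) of every decomposition
#' component whose period falls inside `window`. Used, for example, to strip
#' all superimposed circadian rhythms from a series before re-testing it for
#' 12-h rhythmicity.
#'
#' @param x Numeric series the decomposition was computed from.
#' @param decomposition Its [pencil_decompose()] result.
#' @param window Length-2 numeric, inclusive period window in hours
#'   (e.g. `c(21, 25)` for circadian components).
#' @param timepoints Times of the samples; defaults to `0, dt, 2*dt, ...`.
#' @return Numeric vector: the series with matching components removed.
#' @export
remove_components <- function(x, decomposition, window,
                              timepoints = (seq_along(x) - 1) * decomposition$dt) {
  stopifnot(inherits(decomposition, "pencil_decomposition"))
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be c(low, high) with low <= high")
  }
  comp <- decomposition$components
  hit <- which(comp$period >= window[1] & comp$period <= window[2])
  out <- x
  for (i in hit) {
    out <- out - eval_component(
      timepoints, comp$period[i], comp$decay[i], comp$amplitude[i], comp$phase[i]
    )
  }
  out
}

#' Time of peak of an undamped cosine component
#'
#' Converts a mathematical phase (radians, cosine convention) into the
#' biological phase: the time of peak in hours within one period,
#' `p = ((-phi) mod 2 pi) * T / (2 pi)`, in `[0, T)`.
#'
#' @param phase Phase in radians.
#' @param period Period in hours (> 0).
#' @return Peak time in hours, in `[0, period)`.
#' @examples
#' biological_phase(pi, 12) # peaks at 6 h
#' @export
biological_phase <- function(phase, period) {
  if (any(period <= 0)) abort("`period` must be positive")
  p <- ((-phase) %% (2 * pi)) * period / (2 * pi)
  ifelse(p >= period * (1 - 1e-12), 0, p)
}

#' Decompose every gene of an expression table
#'
#' Runs the matrix-pencil decomposition on each gene of a replicate-averaged
#' long expression table and stacks the per-component results. Genes whose
#' series is constant (no oscillatory component) appear with a single row of
#' `NA` component fields so that every input gene is represented.
#'
#' @param df Long expression tibble with columns `gene`, `time`, `value`
#'   (replicates must be averaged first, see [average_replicates()]).
#' @param k,pencil_fraction Passed to [pencil_decompose()].
#' @return A tibble with columns `gene`, `mean`, `residual_rms`,
#'   `n_components`, `component`, `period`, `decay`, `amplitude`,
#'   `relative_amplitude` (amplitude over the gene mean, `NA` when the mean
#'   is not positive), `phase`, `peak_time`.
#' @export
decompose_genes <- function(df, k = 3, pencil_fraction = 0.5) {
  check_expression_frame(df)
  if ("rep" %in% names(df) && dplyr::n_distinct(df$rep) > 1) {
    abort("`df` has multiple replicates; average them first with average_replicates()")
  }
  genes <- split(df[c("time", "value")], df$gene)
  rows <- lapply(names(genes), function(g) {
    d <- genes[[g]]
    o <- order(d$time)
    times <- d$time[o]
    dt <- check_uniform_times(times)
    if (length(times) < 2 * (2 * as.integer(k) + 1)) {
      abort(sprintf(
        "gene %s: %d samples cannot support k = %d components (need at least %d)",
        g, length(times), as.integer(k), 2 * (2 * as.integer(k) + 1)
      ))
    }
    core <- pencil_core(d$value[o], dt, as.integer(k), pencil_fraction)
    nc <- length(core$period)
    if (nc == 0) {
      tibble(
        gene = g, mean = core$mu, residual_rms = core$residual_rms,
        n_components = 0L, component = NA_integer_, period = NA_real_,
        decay = NA_real_, amplitude = NA_real_, relative_amplitude = NA_real_,
        phase = NA_real_, peak_time = NA_real_
      )
    } else {
      tibble(
        gene = g, mean = core$mu, residual_rms = core$residual_rms,
        n_components = nc, component = seq_len(nc), period = core$period,
        decay = core$decay_cycle, amplitude = core$amplitude,
        relative_amplitude = if (core$mu > 0) core$amplitude / core$mu else NA_real_,
        phase = core$phase, peak_time = core$peak_time
      )
    }
  })
  dplyr::bind_rows(rows)
}
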