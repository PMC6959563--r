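#' Shuffle the time labels of an expression table
#'
#' Applies one random permutation of the timepoint labels, shared across all
#' genes (and replicates), destroying temporal structure while preserving
#' every gene's value multiset and the cross-gene correlation structure.
#' With `per_gene = TRUE` an independent permutation is drawn for each gene
#' instead (sensitivity-analysis mode).
#'
#' @param df Long expression tibble (`gene`, `time`, `value`, optional
#'   `rep`).
#' @param seed Optional seed; the permutation is deterministic given it.
#' @param per_gene Draw an independent permutation per gene (default FALSE).
#' @return The tibble with `time` labels permuted.
#' @export
permute_times <- function(df, seed = NULL, per_gene = FALSE) {
  check_expression_frame(df)
  times <- sort(unique(df$time))
  if (length(times) < 2) abort("need at least two timepoints to permute")
  with_optional_seed(seed, {
    if (per_gene) {
      df |>
        dplyr::mutate(
          time = {
            perm <- sample(times)
            perm[match(.data$time, times)]
          },
          .by = "gene"
        )
    } else {
      perm <- sample(times)
      dplyr::mutate(df, time = perm[match(.data$time, times)])
    }
  })
}

# Count genes of a wide matrix (rows = genes) with at least one component
# matching the criteria. The hot loop of the permutation FDR: works on plain
# numeric rows and skips tibble construction entirely.
count_rhythmic_matrix <- function(mat, dt, criteria, k, pencil_fraction = 0.5) {
  hits <- 0L
  pt <- criteria$peak_time
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    mu <- mean(x)
    if (mu <= criteria$mean_min) next
    core <- pencil_core(x, dt, k, pencil_fraction)
    ok <- core$period >= criteria$period[1] & core$period <= criteria$period[2] &
      core$decay_cycle >= criteria$decay[1] & core$decay_cycle <= criteria$decay[2]
    if (!is.null(pt)) {
      ok <- ok & core$peak_time >= pt[1] & core$peak_time <= pt[2]
    }
    if (any(ok)) hits <- hits + 1L
  }
  hits
}

# Long (replicate-averaged) expression tibble -> genes x timepoints matrix.
expression_wide <- function(df) {
  avg <- average_replicates(df)
  times <- sort(unique(avg$time))
  dt <- check_uniform_times(times)
  wide <- tidyr::pivot_wider(avg,
    id_cols = "gene", names_from = "time",
    values_from = "value", names_sort = TRUE
  )
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$gene
  if (any(is.na(mat))) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "gene %s has no value at time %s",
      rownames(mat)[bad[1]], colnames(mat)[bad[2]]
    ))
  }
  list(mat = mat, dt = dt, times = times)
}

#' Permutation-based FDR of rhythm calls
#'
#' Estimates the false discovery rate of a rhythm class by time-label
#' shuffling: the decomposition-and-classification pipeline is run on the
#' original matrix and on `n_permutations` matrices whose timepoint labels
#' were randomly permuted, and the FDR is the ratio of the mean number of
#' rhythmic genes found in the permuted data (false positives) to the number
#' found in the original data.
#'
#' @param df Long expression tibble; replicates are averaged internally.
#' @param criteria A [rhythm_criteria()] for the class whose FDR is wanted.
#' @param k Components per gene (default 3).
#' @param n_permutations Number of permutation replicates (the full-scale
#'   analysis uses 10,000; smaller counts give a noisier estimate with the
#'   same estimator).
#' @param seed Master seed; one shared column permutation is drawn per
#'   replicate from a derived substream.
#' @param per_gene Use independent per-gene permutations (default FALSE).
#' @param pencil_fraction Passed to the decomposition.
#' @return An object of class `fdr_estimate`: list with `observed`,
#'   `permuted` (integer vector of per-replicate counts), `fdr` (`NA` with
#'   `undefined = TRUE` when nothing is called rhythmic in the original
#'   data), `n_permutations`, `criteria`, `seed`.
#' @export
estimate_fdr <- function(df, criteria, k = 3, n_permutations = 100,
                         seed = 1L, per_gene = FALSE, pencil_fraction = 0.5) {
  stopifnot(inherits(criteria, "rhythm_criteria"))
  if (n_permutations < 1) abort("`n_permutations` must be at least 1")
  wide <- expression_wide(df)
  mat <- wide$mat
  k <- as.integer(k)
  if (ncol(mat) < 2 * (2 * k + 1)) {
    abort(sprintf(
      "matrix has %d timepoints; k = %d needs at least %d",
      ncol(mat), k, 2 * (2 * k + 1)
    ))
  }
  observed <- count_rhythmic_matrix(mat, wide$dt, criteria, k, pencil_fraction)
  nt <- ncol(mat)
  permuted <- vapply(seq_len(n_permutations), function(b) {
    withr::with_seed(derive_seed(seed, b), {
      if (per_gene) {
        pm <- mat
        for (i in seq_len(nrow(pm))) pm[i, ] <- pm[i, sample(nt)]
      } else {
        pm <- mat[, sample(nt), drop = FALSE]
      }
      count_rhythmic_matrix(pm, wide$dt, criteria, k, pencil_fraction)
    })
  }, integer(1))
  fdr <- if (observed > 0) mean(permuted) / observed else NA_real_
  structure(
    list(
      observed = observed, permuted = permuted, fdr = fdr,
      undefined = observed == 0, n_permutations = n_permutations,
      criteria = criteria$name, seed = seed
    ),
    class = "fdr_estimate"
  )
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(
    "Permutation FDR (%s): %d observed rhythmic genes, mean %.2f in %d permutations\n",
    x$criteria, x$observed, mean(x$permuted), x$n_permutations
  ))
  if (x$undefined) {
    cat("  FDR undefined (no rhythmic genes in the original data)\n")
  } else {
    cat(sprintf("  FDR = %.4g\n", x$fdr))
  }
  invisible(x)
}

#' @rdname estimate_fdr
#' @param x An `fdr_estimate`.
#' @param ... Unused.
#' @method tidy fdr_estimate
#' @export
tidy.fdr_estimate <- function(x, ...) {
  tibble(permutation = seq_along(x$permuted), count = x$permuted)
}

#' @rdname estimate_fdr
#' @method glance fdr_estimate
#' @export
glance.fdr_estimate <- function(x, ...) {
  tibble(
    criteria = x$criteria, observed = x$observed,
    permuted_mean = mean(x$permuted), permuted_sd = sd(x$permuted),
    fdr = x$fdr, undefined = x$undefined,
    n_permutations = x$n_permutations
  )
}

#' F-test for a single harmonic
#'
#' Fits a sine/cosine pair at a fixed period against the constant model and
#' returns the standard F-test. A plumbing cross-check for rhythm calls, not
#' a substitute for the decomposition (which estimates period and decay
#' rather than assuming them).
#'
#' @param x Numeric series.
#' @param period Tested period, in the units of `times`.
#' @param times Sample times; default the 0-based index.
#' @return An `htest` with the F statistic, degrees of freedom, and p-value
#'   (`p.value = NA` with a message for a zero-variance series).
#' @export
harmonic_f_test <- function(x, period, times = seq_along(x) - 1) {
  if (length(x) <= 3) abort("series must be longer than 3 points")
  dt <- check_uniform_times(times)
  if (period <= 2 * dt) {
    abort(sprintf("period %g is at or below the Nyquist limit 2 dt = %g", period, 2 * dt))
  }
  if (sd(x) == 0) {
    out <- list(
      statistic = c(F = NA_real_), parameter = c(df1 = 2, df2 = length(x) - 3),
      p.value = NA_real_, method = "Harmonic F-test (zero-variance series)",
      data.name = deparse(substitute(x))
    )
    class(out) <- "htest"
    return(out)
  }
  cs <- cos(2 * pi * times / period)
  sn <- sin(2 * pi * times / period)
  fit <- lm(x ~ cs + sn)
  null_fit <- lm(x ~ 1)
  an <- stats::anova(null_fit, fit)
  out <- list(
    statistic = c(F = an$F[2]),
    parameter = c(df1 = an$Df[2], df2 = an$Res.Df[2]),
    p.value = an$`Pr(>F)`[2],
    method = sprintf("Harmonic F-test at period %g", period),
    data.name = deparse(substitute(x))
  )
  class(out) <- "htest"
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
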