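# Internal validation helpers shared across modules.

# Check a time grid is strictly increasing and uniformly spaced; returns the
# common step. Uniformity tolerance is relative to the step itself so that
# grids stored at reduced precision still validate.
check_uniform_times <- function(times, tol = 1e-6) {
  if (length(times) < 2) {
    abort("need at least two timepoints")
  }
  gaps <- diff(times)
  if (any(gaps <= 0)) {
    i <- which(gaps <= 0)[1]
    abort(sprintf(
      "timepoints must be strictly increasing; offending gap between t = %g and t = %g",
      times[i], times[i + 1]
    ))
  }
  dt <- gaps[1]
  off <- which(abs(gaps - dt) > tol * dt)
  if (length(off)) {
    i <- off[1]
    abort(sprintf(
      "timepoints must be uniformly spaced; gap %g between t = %g and t = %g differs from step %g",
      gaps[i], times[i], times[i + 1], dt
    ))
  }
  dt
}

check_expression_frame <- function(df, require_rep = FALSE) {
  if (!is.data.frame(df)) {
    abort("`df` must be a data frame with columns gene, time, value (optionally rep)")
  }
  need <- c("gene", "time", "value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("`df` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (require_rep && !"rep" %in% names(df)) {
    abort("`df` must have a `rep` column")
  }
  if (!is.numeric(df$time) || !is.numeric(df$value)) {
    abort("`time` and `value` must be numeric")
  }
  if (any(!is.finite(df$value))) {
    bad <- df[!is.finite(df$value), , drop = FALSE]
    abort(sprintf(
      "non-finite expression value for gene %s at time %g",
      bad$gene[1], bad$time[1]
    ))
  }
  invisible(df)
}

# Deterministic substream seed derived from a master seed. Kept below 2^31 so
# it is always a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 1009 * index) %% 2147483647)
}

# Run `code` under a seed when one is given, without disturbing the caller's
# RNG state; with seed = NULL the global stream is used as-is.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
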