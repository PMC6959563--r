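#' Area under a coverage profile
#'
#' Integrates the per-bin signal density over a bin range: each bin
#' contributes `value * bin_width`, so the area is exactly additive over
#' contiguous ranges and linear in the signal. Bounds are 0-based bin
#' offsets in the BED half-open convention: `from = 0, to = n` covers the
#' whole profile.
#'
#' @param profile A coverage profile: tibble with a `value` column (e.g.
#'   from [simulate_coverage_profile()] or [read_bedgraph()]); the
#'   `bin_width` attribute defaults to 1 when absent.
#' @param from,to Integer bin offsets with `0 <= from < to <= nrow(profile)`.
#' @return The area (signal x bases).
#' @export
coverage_auc <- function(profile, from = 0, to = nrow(profile)) {
  if (!"value" %in% names(profile)) abort("`profile` must have a `value` column")
  n <- nrow(profile)
  if (from < 0 || to > n || from >= to) {
    abort(sprintf(
      "invalid range [%g, %g): need 0 <= from < to <= %d", from, to, n
    ))
  }
  bw <- attr(profile, "bin_width") %||% 1
  sum(profile$value[(from + 1):to]) * bw
}

#' Transcription initiation and elongation rate proxies
#'
#' Splits a run-on coverage profile at the pause boundary: the area under
#' the pre-pausing portion (TSS-proximal) proxies the transcription
#' initiation/pausing rate, and the area under the gene body proxies the
#' elongation rate. The two always sum to the area of the whole profile.
#'
#' @param profile A coverage profile with a `value` column.
#' @param boundary Bin index of the pre-pause/body boundary
#'   (`0 < boundary < nrow(profile)`); defaults to the profile's recorded
#'   `boundary` attribute, or, failing that, to `boundary_frac` of the
#'   profile length.
#' @param boundary_frac Fraction of the profile length used when no
#'   boundary is recorded (default 0.1; the pre-pausing extent is a user
#'   choice, not something the data defines).
#' @return A one-row tibble: `initiation`, `elongation`.
#' @export
initiation_elongation_rates <- function(profile, boundary = NULL,
                                        boundary_frac = 0.1) {
  n <- nrow(profile)
  boundary <- boundary %||% attr(profile, "boundary") %||%
    max(1L, round(boundary_frac * n))
  if (boundary <= 0 || boundary >= n) {
    abort(sprintf("`boundary` must lie strictly inside (0, %d)", n))
  }
  tibble(
    initiation = coverage_auc(profile, 0, boundary),
    elongation = coverage_auc(profile, boundary, n)
  )
}

#' Log2 mean-normalize a series
#'
#' `log2(value / mean(values))`; centres a positive series on its mean so
#' that temporal profiles of different overall intensity are comparable.
#'
#' @param x Positive numeric vector.
#' @return Numeric vector of log2 ratios to the mean.
#' @export
log2_mean_normalize <- function(x) {
  if (any(x <= 0)) abort("all values must be positive")
  log2(x / mean(x))
}

#' Select binding sites with bona fide 12-h rhythmic intensity
#'
#' Decomposes each site's binding-intensity time course with the matrix
#' pencil and flags a site as bona fide when some component satisfies the
#' cistrome criteria (by default: period 10.5-13.5 h, per-cycle decay
#' 0.8-1.2, and peak time between 0 h and 3 h, matching the early-day
#' binding peaks of a rhythmic unfolded-protein-response factor).
#'
#' @param df Long tibble with columns `site`, `time`, `value` (uniform
#'   timepoints; typically 48 h at 4-h steps).
#' @param criteria A [rhythm_criteria()]; default the `cistrome_12h`
#'   preset.
#' @param k Components per site; the default 2 suits 12-13 timepoints.
#' @param pencil_fraction Passed to the decomposition.
#' @return A tibble with one row per site: `site`, `bona_fide`, and the
#'   matched component's `period`, `decay`, `amplitude`, `peak_time` (`NA`
#'   when no component matches).
#' @export
select_rhythmic_sites <- function(df, criteria = criteria_preset("cistrome_12h"),
                                  k = 2, pencil_fraction = 0.5) {
  if (!all(c("site", "time", "value") %in% names(df))) {
    abort("`df` must have columns `site`, `time`, `value`")
  }
  comps <- df |>
    dplyr::rename(gene = "site") |>
    decompose_genes(k = k, pencil_fraction = pencil_fraction)
  matched <- classify_components(comps, criteria) |>
    dplyr::filter(.data$matched) |>
    dplyr::slice_max(.data$amplitude, n = 1, by = "gene", with_ties = FALSE) |>
    dplyr::transmute(
      site = .data$gene, bona_fide = TRUE, period = .data$period,
      decay = .data$decay, amplitude = .data$amplitude,
      peak_time = .data$peak_time
    )
  tibble(site = sort(unique(df$site))) |>
    dplyr::left_join(matched, by = "site") |>
    dplyr::mutate(bona_fide = !is.na(.data$bona_fide))
}
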