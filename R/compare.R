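#' Categorize differential rhythmicity between two conditions
#'
#' For one rhythm class (e.g. the 12-h class), compares the decompositions
#' of the same genes under two conditions and labels each gene:
#' `abolished` (rhythm matched in A only), `gained` (B only), `dampened`
#' (both, with strictly smaller relative amplitude in B), `increased`
#' (strictly larger in B), or `unchanged` (both, equal relative amplitude).
#' Relative amplitude (amplitude over gene mean) is compared so that
#' baseline expression shifts between conditions do not masquerade as
#' rhythm changes. When a gene has several matching components, its
#' largest-amplitude matching component represents it.
#'
#' Genes whose rhythm matches in neither condition carry no rhythm of this
#' class to compare and are omitted from the result.
#'
#' @param components_a,components_b Component tables from
#'   [decompose_genes()] for the two conditions (same gene universe).
#' @param criteria A [rhythm_criteria()] for the rhythm class.
#' @return A tibble with one row per gene matched in at least one
#'   condition: `gene`, `category`, `rel_amp_a`, `rel_amp_b`, `peak_a`,
#'   `peak_b`, `period_a`, `period_b`.
#' @export
categorize_rhythms <- function(components_a, components_b, criteria) {
  stopifnot(inherits(criteria, "rhythm_criteria"))
  best_a <- best_match(components_a, criteria)
  best_b <- best_match(components_b, criteria)
  merged <- dplyr::full_join(best_a, best_b,
    by = "gene", suffix = c("_a", "_b")
  )
  merged |>
    dplyr::mutate(
      category = dplyr::case_when(
        !is.na(.data$rel_amp_a) & is.na(.data$rel_amp_b) ~ "abolished",
        is.na(.data$rel_amp_a) & !is.na(.data$rel_amp_b) ~ "gained",
        .data$rel_amp_b < .data$rel_amp_a ~ "dampened",
        .data$rel_amp_b > .data$rel_amp_a ~ "increased",
        .default = "unchanged"
      )
    ) |>
    dplyr::select(
      "gene", "category", "rel_amp_a", "rel_amp_b",
      "peak_a", "peak_b", "period_a", "period_b"
    ) |>
    dplyr::arrange(.data$gene)
}

# Largest-amplitude component matching the criteria, one row per matched
# gene: gene, rel_amp, peak, period.
best_match <- function(components, criteria) {
  classify_components(components, criteria) |>
    dplyr::filter(.data$matched) |>
    dplyr::slice_max(.data$amplitude, n = 1, by = "gene", with_ties = FALSE) |>
    dplyr::transmute(
      gene = .data$gene,
      rel_amp = relative_amplitude(.data$amplitude, .data$mean),
      peak = .data$peak_time,
      period = .data$period
    )
}

#' Count and percentage summary of differential-rhythm categories
#'
#' @param deltas Result of [categorize_rhythms()] (or any tibble with a
#'   `category` column).
#' @return A tibble with one row per category present: `category`, `n`,
#'   `fraction` (exact ratio), `percent` (rounded to one decimal).
#' @export
cohort_summary <- function(deltas) {
  if (!nrow(deltas)) abort("`deltas` must be non-empty")
  deltas |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(
      fraction = .data$n / sum(.data$n),
      percent = round(100 * .data$fraction, 1)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Overlap of two gene sets
#'
#' @param set_a,set_b Character vectors of gene identifiers (duplicates are
#'   ignored).
#' @return A one-row tibble: `common`, `only_a`, `only_b`.
#' @export
overlap_summary <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  tibble(
    common = length(intersect(set_a, set_b)),
    only_a = length(setdiff(set_a, set_b)),
    only_b = length(setdiff(set_b, set_a))
  )
}

#' Harmonic period lock between an ultradian and a circadian rhythm
#'
#' Checks whether a harmonic (ultradian) period is an integer fraction of a
#' circadian period: the nearest integer ratio
#' `k = round(period_circadian / period_harmonic)` gives the implied
#' circadian period `k * period_harmonic`, and the rhythms are flagged as
#' period-locked when the implied and observed circadian periods agree to
#' within the tolerance. E.g. 7.3 h x 3 = 21.9 h and 10.8 h x 2 = 21.6 h
#' both sit within 2% of a 21.6-h circadian rhythm.
#'
#' @param period_harmonic Ultradian period(s), hours.
#' @param period_circadian Circadian period(s), hours.
#' @param tolerance Relative tolerance for the lock flag (default 0.05).
#' @return A tibble with columns `period_harmonic`, `period_circadian`,
#'   `k`, `implied_period`, `locked`.
#' @export
harmonic_lock_ratio <- function(period_harmonic, period_circadian,
                                tolerance = 0.05) {
  if (any(period_harmonic <= 0) || any(period_circadian <= 0)) {
    abort("periods must be positive")
  }
  k <- round(period_circadian / period_harmonic)
  implied <- k * period_harmonic
  tibble(
    period_harmonic = period_harmonic,
    period_circadian = period_circadian,
    k = as.integer(k),
    implied_period = implied,
    locked = abs(implied - period_circadian) / period_circadian <= tolerance
  )
}
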