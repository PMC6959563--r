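#' Rhythm classification criteria
#'
#' A set of inclusive windows a decomposition component must fall in to count
#' as a rhythm of a given class: period window (hours), per-cycle decay
#' window (1 = sustained oscillation), a minimum mean expression for the
#' gene, and an optional peak-time window (hours) for selecting, e.g.,
#' binding sites that peak in a narrow phase interval.
#'
#' @param name Label for the criteria set.
#' @param period Length-2 numeric, inclusive period window `[lo, hi]`.
#' @param decay Length-2 numeric, inclusive per-cycle decay window.
#' @param mean_min Gene mean expression must be strictly larger than this.
#' @param peak_time Optional length-2 numeric, inclusive peak-time window.
#' @return An object of class `rhythm_criteria`.
#' @seealso [criteria_preset()] for the published window sets.
#' @export
rhythm_criteria <- function(name, period, decay = c(0.8, 1.2), mean_min = 0.1,
                            peak_time = NULL) {
  stopifnot(length(period) == 2, length(decay) == 2)
  if (period[1] >= period[2]) abort("period window must have lo < hi")
  if (decay[1] >= decay[2]) abort("decay window must have lo < hi")
  if (!is.null(peak_time)) {
    stopifnot(length(peak_time) == 2)
    if (peak_time[1] > peak_time[2]) abort("peak-time window must have lo <= hi")
  }
  structure(
    list(
      name = name, period = as.numeric(period), decay = as.numeric(decay),
      mean_min = as.numeric(mean_min), peak_time = peak_time
    ),
    class = "rhythm_criteria"
  )
}

#' @export
print.rhythm_criteria <- function(x, ...) {
  cat(sprintf(
    "Rhythm criteria '%s': period [%g, %g] h, decay [%g, %g], mean > %g%s\n",
    x$name, x$period[1], x$period[2], x$decay[1], x$decay[2], x$mean_min,
    if (is.null(x$peak_time)) "" else {
      sprintf(", peak time [%g, %g] h", x$peak_time[1], x$peak_time[2])
    }
  ))
  invisible(x)
}

# The published criteria windows for each dataset and rhythm class.
criteria_presets <- list(
  liver_circadian = list(period = c(21, 25), decay = c(0.8, 1.2), mean_min = 0.1),
  liver_12h = list(period = c(10.5, 13.5), decay = c(0.8, 1.2), mean_min = 0.1),
  liver_8h = list(period = c(7, 9), decay = c(0.8, 1.2), mean_min = 0.1),
  mmh_d3_circadian = list(period = c(20.5, 23.5), decay = c(0.9, 1.1), mean_min = 0),
  mmh_d3_12h = list(period = c(9.5, 12.5), decay = c(0.9, 1.1), mean_min = 0),
  cistrome_12h = list(
    period = c(10.5, 13.5), decay = c(0.8, 1.2), mean_min = 0,
    peak_time = c(0, 3)
  )
)

#' Published rhythm-criteria presets
#'
#' Returns the classification windows used for each dataset: mouse liver in
#' vivo (circadian 21-25 h, ~12-h 10.5-13.5 h, ~8-h 7-9 h; decay 0.8-1.2;
#' mean FPKM > 0.1), serum-synchronized MMH-D3 hepatocytes (circadian
#' 20.5-23.5 h, ~12-h 9.5-12.5 h; decay 0.9-1.1), and the ChIP-Seq cistrome
#' rule for bona fide 12-h binding sites (period 10.5-13.5 h, decay 0.8-1.2,
#' peak time 0-3 h).
#'
#' @param name One of `"liver_circadian"`, `"liver_12h"`, `"liver_8h"`,
#'   `"mmh_d3_circadian"`, `"mmh_d3_12h"`, `"cistrome_12h"`.
#' @return A [rhythm_criteria()] object.
#' @export
criteria_preset <- function(name) {
  if (!name %in% names(criteria_presets)) {
    abort(sprintf(
      "unknown preset '%s'; valid presets: %s",
      name, paste(names(criteria_presets), collapse = ", ")
    ))
  }
  p <- criteria_presets[[name]]
  rhythm_criteria(
    name,
    period = p$period, decay = p$decay, mean_min = p$mean_min,
    peak_time = p$peak_time
  )
}

#' Flag decomposition components matching a criteria set
#'
#' A component matches when its period and decay fall inside the inclusive
#' windows, the gene mean is strictly above the expression threshold, and
#' (when the criteria set one) its peak time falls inside the peak-time
#' window.
#'
#' @param components Component table from [decompose_genes()] (or
#'   [tidy()] of a single decomposition plus a `mean` column).
#' @param criteria A [rhythm_criteria()] object.
#' @return The component table with a logical `matched` column added.
#' @export
classify_components <- function(components, criteria) {
  stopifnot(inherits(criteria, "rhythm_criteria"))
  need <- c("period", "decay", "mean")
  missing <- setdiff(need, names(components))
  if (length(missing)) {
    abort(paste0("`components` is missing column(s): ", paste(missing, collapse = ", ")))
  }
  matched <- !is.na(components$period) &
    components$period >= criteria$period[1] &
    components$period <= criteria$period[2] &
    components$decay >= criteria$decay[1] &
    components$decay <= criteria$decay[2] &
    components$mean > criteria$mean_min
  if (!is.null(criteria$peak_time)) {
    matched <- matched &
      components$peak_time >= criteria$peak_time[1] &
      components$peak_time <= criteria$peak_time[2]
  }
  dplyr::mutate(components, matched = matched)
}

#' Gene-level rhythm calls with dominant-class labels
#'
#' A gene belongs to a rhythm class whenever any of its superimposed
#' components matches that class's criteria, so one gene can be, e.g., both
#' circadian and 12-h cycling. The dominant class is decided by the single
#' largest-amplitude component of the gene: if that component matches some
#' class the gene is dominant for it, otherwise the gene has no dominant
#' class. Dominant labels are therefore mutually exclusive across classes.
#'
#' @param components Component table from [decompose_genes()].
#' @param criteria Named list of [rhythm_criteria()] objects, one per class
#'   (defaults to the three liver presets).
#' @return A tibble with one row per gene: `gene`, `mean`, one logical
#'   column per class, and `dominant` (class name or `NA`).
#' @export
call_genes <- function(components,
                       criteria = list(
                         circadian = criteria_preset("liver_circadian"),
                         twelvehour = criteria_preset("liver_12h"),
                         eighthour = criteria_preset("liver_8h")
                       )) {
  if (is.null(names(criteria)) || any(names(criteria) == "")) {
    abort("`criteria` must be a named list of rhythm_criteria objects")
  }
  match_mat <- vapply(
    criteria,
    function(cr) classify_components(components, cr)$matched,
    logical(nrow(components))
  )
  match_mat <- matrix(match_mat,
    nrow = nrow(components),
    dimnames = list(NULL, names(criteria))
  )
  per_comp <- dplyr::bind_cols(
    components[c("gene", "mean", "amplitude")],
    as_tibble(match_mat)
  )
  flags <- per_comp |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(names(criteria)), ~ any(.x, na.rm = TRUE)),
      .by = c("gene", "mean")
    )
  # dominant class: class matched by the gene's single largest-amplitude
  # component (amplitude ties broken as in the decomposition ranking)
  dominant <- per_comp |>
    dplyr::filter(!is.na(.data$amplitude)) |>
    dplyr::slice_max(.data$amplitude, n = 1, by = "gene", with_ties = FALSE) |>
    dplyr::mutate(
      dominant = apply(
        dplyr::pick(dplyr::all_of(names(criteria))), 1,
        function(m) if (any(m)) names(criteria)[which(m)[1]] else NA_character_
      )
    ) |>
    dplyr::select("gene", "dominant")
  flags |>
    dplyr::left_join(dominant, by = "gene") |>
    dplyr::arrange(.data$gene)
}

#' Relative amplitude of an oscillation
#'
#' Amplitude divided by the gene's mean expression, making amplitudes
#' comparable across expression levels.
#'
#' @param amplitude Component amplitude (expression units, >= 0).
#' @param mean Gene mean expression (> 0).
#' @return The ratio `amplitude / mean`.
#' @export
relative_amplitude <- function(amplitude, mean) {
  if (any(mean <= 0)) abort("`mean` must be positive")
  amplitude / mean
}
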