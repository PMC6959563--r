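# Parse timepoint headers like "CT0", "ZT12", "CT0_r1", or bare "14" /
# "14_r2" into hours and replicate numbers.
parse_time_labels <- function(labels) {
  m <- regmatches(
    labels,
    regexec("^(?:CT|ZT)?(-?[0-9]+(?:\\.[0-9]+)?)(?:_r([0-9]+))?$", labels)
  )
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad)) {
    abort(sprintf("cannot parse timepoint label '%s'", labels[bad[1]]))
  }
  tibble(
    label = labels,
    time = vapply(m, function(g) as.numeric(g[2]), numeric(1)),
    rep = vapply(m, function(g) {
      if (g[3] == "") 1L else as.integer(g[3])
    }, integer(1))
  )
}

#' Read a wide expression matrix TSV into a long tibble
#'
#' Expects a header of timepoint labels ("CT0", "ZT2", or bare hours, with
#' optional "_r1"/"_r2" replicate suffixes) and one row per gene, the first
#' column holding unique gene identifiers. Timepoints are validated to be
#' uniformly spaced and replicate structure to be complete.
#'
#' @param path Path to a tab-separated file.
#' @return A long tibble with columns `gene`, `time`, `rep`, `value` (the
#'   `rep` column is dropped when the file has a single replicate).
#' @export
read_expression_matrix <- function(path) {
  wide <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(wide) < 3) abort("expression matrix needs a gene column and >= 2 timepoints")
  genes <- wide[[1]]
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene id '%s'", genes[duplicated(genes)][1]))
  }
  labels <- parse_time_labels(names(wide)[-1])
  vals <- suppressWarnings(
    vapply(wide[-1], as.numeric, numeric(nrow(wide)))
  )
  vals <- matrix(vals, nrow = nrow(wide))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric or missing value at gene '%s', column '%s'",
      genes[bad[1]], labels$label[bad[2]]
    ))
  }
  wide[-1] <- as.data.frame(vals)
  per_rep <- split(labels$time, labels$rep)
  times <- sort(unique(labels$time))
  for (r in names(per_rep)) {
    if (!setequal(per_rep[[r]], times)) {
      abort(sprintf("replicate %s does not cover all timepoints", r))
    }
  }
  check_uniform_times(times)
  long <- wide |>
    dplyr::rename(gene = 1) |>
    tidyr::pivot_longer(-"gene", names_to = "label", values_to = "value") |>
    dplyr::left_join(labels, by = "label") |>
    dplyr::select("gene", "time", "rep", "value") |>
    dplyr::arrange(.data$gene, .data$rep, .data$time)
  if (dplyr::n_distinct(long$rep) == 1) long$rep <- NULL
  long
}

#' Write a long expression tibble as a wide TSV
#'
#' Inverse of [read_expression_matrix()]: columns are labelled `CT<h>` (or
#' `CT<h>_r<k>` with replicates), values are serialized at full precision so
#' a write/read round trip is lossless.
#'
#' @param df Long expression tibble (`gene`, `time`, `value`, optional
#'   `rep`).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_expression_matrix <- function(df, path) {
  check_expression_frame(df)
  has_rep <- "rep" %in% names(df) && dplyr::n_distinct(df$rep) > 1
  lab <- if (has_rep) {
    sprintf("CT%g_r%d", df$time, df$rep)
  } else {
    sprintf("CT%g", df$time)
  }
  wide <- df |>
    dplyr::mutate(label = lab) |>
    dplyr::select("gene", "label", "value") |>
    tidyr::pivot_wider(names_from = "label", values_from = "value") |>
    dplyr::rename(gene_id = "gene")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(df)
}

#' Read a bedGraph-like coverage file
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open
#' intervals, no header.
#'
#' @param path Path to the file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "ciid", progress = FALSE
  )
}

#' Write a results table as TSV
#'
#' Tab-delimited, `.` decimal separator, header row, trailing newline, full
#' numeric precision.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `df`, invisibly.
#' @export
write_results_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(df)
}

#' Write a results list as JSON
#'
#' Stable key order (insertion order), scalars unboxed, full precision.
#'
#' @param x A named list (or similar) of results.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: classification presets,
#' number of components, pencil fraction, expression threshold, optional
#' detrending, permutation count for the FDR stage, phase circle, and the
#' master seed. All downstream randomness derives from the single seed.
#'
#' @param input Long expression tibble, or path to a wide TSV.
#' @param input_b Optional second condition (tibble or path) for the
#'   differential-rhythm stage.
#' @param out_dir Output directory for result tables (created if needed);
#'   `NULL` keeps everything in memory.
#' @param k Components per gene.
#' @param pencil_fraction Pencil window fraction.
#' @param threshold Background expression threshold.
#' @param detrend_order Polynomial detrend order, or `NULL` to skip.
#' @param presets Named character vector mapping class names to
#'   [criteria_preset()] names.
#' @param fdr_class Class (name in `presets`) whose permutation FDR is
#'   estimated; `NULL` skips the stage.
#' @param n_permutations Permutation count for the FDR stage.
#' @param phase_period Circle (hours) for the phase-summary stage.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, input_b = NULL, out_dir = NULL,
                            k = 3, pencil_fraction = 0.5, threshold = 0.1,
                            detrend_order = NULL,
                            presets = c(
                              circadian = "liver_circadian",
                              twelvehour = "liver_12h",
                              eighthour = "liver_8h"
                            ),
                            fdr_class = NULL, n_permutations = 100,
                            phase_period = 12, seed = 1L) {
  if (is.character(input) && !file.exists(input)) {
    abort(sprintf("input file '%s' does not exist", input))
  }
  if (is.character(input_b) && !is.null(input_b) && !file.exists(input_b)) {
    abort(sprintf("input file '%s' does not exist", input_b))
  }
  for (p in presets) criteria_preset(p) # validates names early
  if (!is.null(fdr_class) && !fdr_class %in% names(presets)) {
    abort(sprintf("fdr_class '%s' is not a name of `presets`", fdr_class))
  }
  structure(
    list(
      input = input, input_b = input_b, out_dir = out_dir, k = k,
      pencil_fraction = pencil_fraction, threshold = threshold,
      detrend_order = detrend_order, presets = presets,
      fdr_class = fdr_class, n_permutations = n_permutations,
      phase_period = phase_period, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

load_input <- function(input) {
  if (is.character(input)) read_expression_matrix(input) else as_tibble(input)
}

preprocess_stage <- function(df, config) {
  avg <- average_replicates(df)
  if (!is.null(config$detrend_order)) {
    avg <- polynomial_detrend(avg, order = config$detrend_order)
  }
  mask <- expression_filter(avg, threshold = config$threshold)
  list(
    averaged = dplyr::semi_join(avg, dplyr::filter(mask, .data$expressed),
      by = "gene"
    ),
    filter = mask
  )
}

#' Run the full rhythm-identification pipeline
#'
#' Orchestrates preprocessing (replicate averaging, optional polynomial
#' detrend, background filtering), per-gene matrix-pencil decomposition,
#' rhythm classification, optional permutation FDR, phase summaries of the
#' 12-h class, and (when a second condition is supplied) differential-rhythm
#' categorization. All stage outputs are returned as a named bundle and,
#' when `out_dir` is set, written as TSV/JSON files alongside a manifest
#' recording the configuration, seed, and gene counts surviving each stage.
#'
#' @param config A [pipeline_config()].
#' @return A list (invisibly when writing to disk) with elements `filter`,
#'   `components`, `calls`, `fdr`, `phases`, `deltas`, `delta_summary`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  criteria <- lapply(config$presets, criteria_preset)
  df <- load_input(config$input)
  check_expression_frame(df)

  pre <- preprocess_stage(df, config)
  comps <- decompose_genes(pre$averaged,
    k = config$k,
    pencil_fraction = config$pencil_fraction
  )
  calls <- call_genes(comps, criteria)

  fdr <- NULL
  if (!is.null(config$fdr_class) && config$n_permutations > 0) {
    fdr <- estimate_fdr(pre$averaged, criteria[[config$fdr_class]],
      k = config$k, n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, 101L),
      pencil_fraction = config$pencil_fraction
    )
  }

  tw <- criteria[["twelvehour"]] %||% criteria[[1]]
  matched12 <- classify_components(comps, tw) |> dplyr::filter(.data$matched)
  phases <- polar_histogram(matched12$peak_time,
    period = config$phase_period, n_bins = 12
  )

  deltas <- NULL
  delta_summary <- NULL
  if (!is.null(config$input_b)) {
    df_b <- load_input(config$input_b)
    pre_b <- preprocess_stage(df_b, config)
    comps_b <- decompose_genes(pre_b$averaged,
      k = config$k,
      pencil_fraction = config$pencil_fraction
    )
    deltas <- categorize_rhythms(comps, comps_b, tw)
    delta_summary <- cohort_summary(deltas)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rhythmpencil")),
    seed = config$seed,
    config = config[c(
      "k", "pencil_fraction", "threshold", "detrend_order",
      "presets", "fdr_class", "n_permutations", "phase_period"
    )],
    stages = c(
      "preprocess", "decompose", "classify",
      if (!is.null(fdr)) "fdr",
      "phases",
      if (!is.null(deltas)) "compare"
    ),
    n_genes_input = dplyr::n_distinct(df$gene),
    n_genes_expressed = sum(pre$filter$expressed),
    n_components = sum(!is.na(comps$component))
  )

  bundle <- list(
    filter = pre$filter, components = comps, calls = calls,
    fdr = fdr, phases = phases, deltas = deltas,
    delta_summary = delta_summary, manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$out_dir, name)
    write_results_table(pre$filter, out("expression_filter.tsv"))
    write_results_table(comps, out("components.tsv"))
    write_results_table(calls, out("calls.tsv"))
    write_results_table(phases, out("phase_histogram.tsv"))
    if (!is.null(fdr)) write_results_json(glance(fdr), out("fdr.json"))
    if (!is.null(deltas)) {
      write_results_table(deltas, out("deltas.tsv"))
      write_results_table(delta_summary, out("delta_summary.tsv"))
    }
    write_results_json(manifest, out("manifest.json"))
    return(invisible(bundle))
  }
  bundle
}
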