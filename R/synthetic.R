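#' Specification for a synthetic rhythmic-expression cohort
#'
#' Describes the statistical structure the rhythm pipeline assumes in real
#' data so that cohorts with known ground truth can be generated: 24
#' timepoints at 2-h steps over 48 h in duplicate, a log-normal baseline with
#' a non-expressed fraction below 0.1 FPKM, genes carrying 0-3 superimposed
#' damped oscillations near 24/12/8 h, 12-h peak times concentrated bimodally
#' near dawn (CT0-2) and dusk (CT12-14), circadian peak times uniform over
#' the day, and a paired "knockout" condition in which 12-h components are
#' abolished, dampened, or increased.
#'
#' @param n_genes Number of genes (> 0).
#' @param timepoints Sampling times in hours, strictly increasing and
#'   uniformly spaced (default CT0-CT46 at 2-h steps).
#' @param n_replicates Replicates per timepoint (default 2).
#' @param class_fractions Named proportions over gene classes `null`,
#'   `circadian`, `twelvehour`, `mixed` (24 h + 12 h), `eighthour`,
#'   `subthreshold`; must sum to 1.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean expression of expressed genes.
#' @param noise_frac Additive Gaussian noise scale, as a fraction of each
#'   gene's baseline mean.
#' @param rel_amplitude Length-2 range of component relative amplitudes
#'   (amplitude / baseline mean), drawn uniformly.
#' @param circadian_period,twelvehour_period,eighthour_period Length-2
#'   period ranges (hours) for each component class, drawn uniformly; the
#'   defaults sit inside the published classification windows.
#' @param decay_range Length-2 range of per-cycle decay, drawn uniformly.
#' @param phase_model List with `modes` (hours), `sd` (hours), and `weights`
#'   describing the two-mode wrapped-normal mixture of 12-h peak times on
#'   the 24-h day (defaults: modes 0 and 12, sd 1 h, equal weights).
#' @param effect_fractions Named proportions over the paired-condition
#'   effects `abolished`, `dampened`, `increased`, `unchanged`, applied to
#'   genes carrying a 12-h component; must sum to 1. Defaults to the
#'   54.5/31.6/13.9 percent split observed among affected hepatic 12-h genes.
#' @param dampen_factor Multiplier (< 1) applied to 12-h amplitudes of
#'   dampened genes in condition B.
#' @param boost_factor Multiplier (> 1) applied to 12-h amplitudes of
#'   increased genes in condition B.
#' @param subthreshold_mean Length-2 range of baseline means for the
#'   sub-threshold class (below the 0.1 background cut).
#' @param seed Master seed; every stream the generator uses is derived from
#'   it deterministically.
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [simulate_cohort()], [simulate_two_conditions()]
#' @export
synthetic_spec <- function(n_genes,
                           timepoints = seq(0, 46, by = 2),
                           n_replicates = 2,
                           class_fractions = c(
                             null = 0.30, circadian = 0.15, twelvehour = 0.15,
                             mixed = 0.15, eighthour = 0.10, subthreshold = 0.15
                           ),
                           baseline_meanlog = 1.5,
                           baseline_sdlog = 1,
                           noise_frac = 0.05,
                           rel_amplitude = c(0.1, 0.5),
                           circadian_period = c(21.5, 24.5),
                           twelvehour_period = c(11.1, 12.6),
                           eighthour_period = c(7.2, 8.8),
                           decay_range = c(0.9, 1.1),
                           phase_model = list(
                             modes = c(0, 12), sd = 1, weights = c(0.5, 0.5)
                           ),
                           effect_fractions = c(
                             abolished = 0.545, dampened = 0.316,
                             increased = 0.139, unchanged = 0
                           ),
                           dampen_factor = 0.5,
                           boost_factor = 2,
                           subthreshold_mean = c(0.01, 0.09),
                           seed = 1L) {
  if (n_genes < 1) abort("`n_genes` must be at least 1")
  check_uniform_times(timepoints)
  classes <- c("null", "circadian", "twelvehour", "mixed", "eighthour", "subthreshold")
  missing <- setdiff(classes, names(class_fractions))
  if (length(missing)) {
    abort(paste0("class_fractions missing: ", paste(missing, collapse = ", ")))
  }
  class_fractions <- class_fractions[classes]
  if (any(class_fractions < 0 | class_fractions > 1)) {
    abort("class_fractions must lie in [0, 1]")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    abort(sprintf("class_fractions must sum to 1 (got %.12g)", sum(class_fractions)))
  }
  effects <- c("abolished", "dampened", "increased", "unchanged")
  missing <- setdiff(effects, names(effect_fractions))
  if (length(missing)) {
    abort(paste0("effect_fractions missing: ", paste(missing, collapse = ", ")))
  }
  effect_fractions <- effect_fractions[effects]
  if (any(effect_fractions < 0 | effect_fractions > 1)) {
    abort("effect_fractions must lie in [0, 1]")
  }
  if (abs(sum(effect_fractions) - 1) > 1e-9) {
    abort(sprintf("effect_fractions must sum to 1 (got %.12g)", sum(effect_fractions)))
  }
  if (dampen_factor >= 1 || dampen_factor <= 0) {
    abort("`dampen_factor` must be in (0, 1): a factor >= 1 is not dampening")
  }
  if (boost_factor <= 1) abort("`boost_factor` must be > 1")
  if (noise_frac < 0) abort("`noise_frac` must be non-negative")
  structure(
    list(
      n_genes = as.integer(n_genes), timepoints = as.numeric(timepoints),
      n_replicates = as.integer(n_replicates),
      class_fractions = class_fractions,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      noise_frac = noise_frac, rel_amplitude = rel_amplitude,
      circadian_period = circadian_period,
      twelvehour_period = twelvehour_period,
      eighthour_period = eighthour_period,
      decay_range = decay_range, phase_model = phase_model,
      effect_fractions = effect_fractions,
      dampen_factor = dampen_factor, boost_factor = boost_factor,
      subthreshold_mean = subthreshold_mean,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Simulate one replicate-resolved expression series
#'
#' Forward model of the decomposition:
#' `value(t) = mean + sum_k A_k d_k^(t/T_k) cos(2 pi t/T_k + phi_k) + e`,
#' with `e ~ N(0, noise_sd)` drawn independently per replicate and
#' timepoint, and `phi_k` derived from the component's peak time.
#'
#' @param components Tibble (or data frame) with columns `period`, `decay`,
#'   `amplitude`, `peak_time`; zero rows give a constant series.
#' @param mean Baseline expression level (>= 0).
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param timepoints Uniformly spaced sampling times (hours).
#' @param replicates Number of replicates.
#' @param seed Optional seed; the same seed reproduces the series exactly.
#' @return A tibble with columns `time`, `rep`, `value`.
#' @export
simulate_series <- function(components, mean, noise_sd, timepoints,
                            replicates = 1, seed = NULL) {
  check_uniform_times(timepoints)
  if (mean < 0) abort("`mean` must be non-negative")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  signal <- rep(mean, length(timepoints))
  for (i in seq_len(NROW(components))) {
    phi <- (-2 * pi * components$peak_time[i] / components$period[i]) %% (2 * pi)
    signal <- signal + eval_component(
      timepoints, components$period[i], components$decay[i],
      components$amplitude[i], phi
    )
  }
  with_optional_seed(seed, {
    tidyr::expand_grid(rep = seq_len(replicates), time = timepoints) |>
      dplyr::mutate(
        value = rep(signal, times = replicates) +
          rnorm(replicates * length(timepoints), 0, noise_sd)
      ) |>
      dplyr::select("time", "rep", "value")
  })
}

# Draw n peak times for 12-h components from the two-mode wrapped-normal
# mixture on the 24-h day; returned on the 24-h circle.
draw_bimodal_peaks <- function(n, phase_model) {
  mode <- sample(seq_along(phase_model$modes), n,
    replace = TRUE, prob = phase_model$weights
  )
  (phase_model$modes[mode] + rnorm(n, 0, phase_model$sd)) %% 24
}

runif_range <- function(n, range) runif(n, range[1], range[2])

# Draw the true components for one gene of a given class. Peak times are
# stored modulo the component period.
draw_components <- function(class, baseline, spec) {
  comp <- function(period, peak24) {
    tibble(
      period = period,
      decay = runif_range(length(period), spec$decay_range),
      amplitude = runif_range(length(period), spec$rel_amplitude) * baseline,
      peak_time = peak24 %% period
    )
  }
  switch(class,
    null = tibble(
      period = numeric(0), decay = numeric(0),
      amplitude = numeric(0), peak_time = numeric(0)
    ),
    circadian = comp(runif_range(1, spec$circadian_period), runif(1, 0, 24)),
    twelvehour = ,
    subthreshold = comp(
      runif_range(1, spec$twelvehour_period),
      draw_bimodal_peaks(1, spec$phase_model)
    ),
    eighthour = comp(runif_range(1, spec$eighthour_period), runif(1, 0, 24)),
    mixed = dplyr::bind_rows(
      comp(runif_range(1, spec$circadian_period), runif(1, 0, 24)),
      comp(
        runif_range(1, spec$twelvehour_period),
        draw_bimodal_peaks(1, spec$phase_model)
      )
    )
  )
}

# Build the per-gene truth (classes, baselines, components) for a spec.
draw_truth <- function(spec) {
  n <- spec$n_genes
  gene <- sprintf("gene_%05d", seq_len(n))
  class <- sample(names(spec$class_fractions), n,
    replace = TRUE, prob = spec$class_fractions
  )
  baseline <- rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  sub <- class == "subthreshold"
  baseline[sub] <- runif_range(sum(sub), spec$subthreshold_mean)
  comps <- lapply(seq_len(n), function(i) {
    draw_components(class[i], baseline[i], spec)
  })
  list(gene = gene, class = class, baseline = baseline, components = comps)
}

truth_table <- function(truth) {
  purrr::map2(truth$components, seq_along(truth$gene), function(cc, i) {
    if (nrow(cc) == 0) {
      tibble(
        gene = truth$gene[i], class = truth$class[i],
        baseline = truth$baseline[i], period = NA_real_, decay = NA_real_,
        amplitude = NA_real_, peak_time = NA_real_
      )
    } else {
      tibble(
        gene = truth$gene[i], class = truth$class[i],
        baseline = truth$baseline[i]
      ) |>
        dplyr::bind_cols(cc)
    }
  }) |>
    dplyr::bind_rows()
}

# Noise-added expression table for a drawn truth; substream index
# distinguishes conditions so paired matrices get independent noise.
truth_expression <- function(truth, spec, stream) {
  n <- length(truth$gene)
  tp <- spec$timepoints
  reps <- spec$n_replicates
  signal <- vapply(seq_len(n), function(i) {
    cc <- truth$components[[i]]
    s <- rep(truth$baseline[i], length(tp))
    for (j in seq_len(nrow(cc))) {
      phi <- (-2 * pi * cc$peak_time[j] / cc$period[j]) %% (2 * pi)
      s <- s + eval_component(tp, cc$period[j], cc$decay[j], cc$amplitude[j], phi)
    }
    s
  }, numeric(length(tp)))
  # flatten to gene (outer) x rep x time (inner), matching expand_grid below
  sig_long <- as.vector(signal[, rep(seq_len(n), each = reps), drop = FALSE])
  withr::with_seed(derive_seed(spec$seed, stream), {
    noise <- rnorm(
      n * length(tp) * reps,
      0, rep(spec$noise_frac * truth$baseline, each = length(tp) * reps)
    )
    tidyr::expand_grid(gene = truth$gene, rep = seq_len(reps), time = tp) |>
      dplyr::mutate(value = sig_long + noise) |>
      dplyr::select("gene", "time", "rep", "value")
  })
}

#' Simulate an expression cohort with ground truth
#'
#' Draws gene classes, baselines, and true oscillation components per the
#' spec, and returns the noisy replicate-resolved expression table together
#' with the generator-side ground truth for recovery testing.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `expression` (tibble `gene`, `time`, `rep`,
#'   `value`) and `truth` (tibble `gene`, `class`, `baseline`, and one row
#'   per true component with `period`, `decay`, `amplitude`, `peak_time`;
#'   genes without components carry a single all-`NA` component row).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- withr::with_seed(derive_seed(spec$seed, 1L), draw_truth(spec))
  list(
    expression = truth_expression(truth, spec, stream = 2L),
    truth = truth_table(truth)
  )
}

#' Simulate paired condition matrices with 12-h effects
#'
#' Generates condition A per the spec, then regenerates condition B from the
#' same ground truth with each gene's 12-h component amplitude set to zero
#' (`abolished`), multiplied by `dampen_factor` (`dampened`), or multiplied
#' by `boost_factor` (`increased`) according to effect labels sampled from
#' `effect_fractions` among the genes that carry a 12-h component. All other
#' components are unchanged; the two conditions use independent noise draws.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression_a`, `expression_b` (long tibbles) and
#'   `truth` (as in [simulate_cohort()], plus an `effect` label column and
#'   `amplitude_b`, the component amplitude in condition B).
#' @export
simulate_two_conditions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- withr::with_seed(derive_seed(spec$seed, 1L), draw_truth(spec))
  lo <- spec$twelvehour_period[1]
  hi <- spec$twelvehour_period[2]
  has12 <- vapply(truth$components, function(cc) {
    any(cc$period >= lo & cc$period <= hi)
  }, logical(1))
  effect <- rep("unchanged", length(truth$gene))
  effect[has12] <- withr::with_seed(
    derive_seed(spec$seed, 3L),
    sample(names(spec$effect_fractions), sum(has12),
      replace = TRUE, prob = spec$effect_fractions
    )
  )
  factors <- c(
    abolished = 0, dampened = spec$dampen_factor,
    increased = spec$boost_factor, unchanged = 1
  )
  truth_b <- truth
  truth_b$components <- purrr::map2(
    truth$components, effect,
    function(cc, eff) {
      is12 <- cc$period >= lo & cc$period <= hi
      cc$amplitude[is12] <- cc$amplitude[is12] * factors[[eff]]
      cc
    }
  )
  tt <- truth_table(truth) |>
    dplyr::mutate(effect = effect[match(.data$gene, truth$gene)])
  tt$amplitude_b <- truth_table(truth_b)$amplitude
  list(
    expression_a = truth_expression(truth, spec, stream = 2L),
    expression_b = truth_expression(truth_b, spec, stream = 4L),
    truth = tt
  )
}

#' Simulate a two-plateau coverage profile
#'
#' Piecewise-constant per-base signal mimicking a run-on sequencing profile:
#' a pre-pausing plateau of `pre_pause_length` bins at `pre_pause_level`
#' followed by a gene-body plateau of `body_length` bins at `body_level`,
#' plus optional additive Gaussian noise. The boundary bin index is recorded
#' as an attribute for [initiation_elongation_rates()].
#'
#' @param pre_pause_level,body_level Signal densities (>= 0).
#' @param pre_pause_length,body_length Segment lengths in bins (> 0).
#' @param noise_sd Additive noise standard deviation.
#' @param bin_width Bin width in bases (default 1).
#' @param seed Optional seed for the noise.
#' @return A tibble of class `coverage_profile` with columns `position`
#'   (0-based bin start) and `value`, and attributes `boundary` (bin index
#'   of the pre-pause/body boundary) and `bin_width`.
#' @export
simulate_coverage_profile <- function(pre_pause_level, body_level,
                                      pre_pause_length, body_length,
                                      noise_sd = 0, bin_width = 1,
                                      seed = NULL) {
  if (pre_pause_level < 0 || body_level < 0) abort("levels must be non-negative")
  if (pre_pause_length <= 0 || body_length <= 0) abort("segment lengths must be positive")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  n1 <- as.integer(pre_pause_length)
  n2 <- as.integer(body_length)
  values <- c(rep(pre_pause_level, n1), rep(body_level, n2))
  values <- with_optional_seed(seed, values + rnorm(n1 + n2, 0, noise_sd))
  out <- tibble(
    position = (seq_len(n1 + n2) - 1) * bin_width,
    value = values
  )
  structure(out,
    boundary = n1, bin_width = bin_width,
    class = c("coverage_profile", class(out))
  )
}
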