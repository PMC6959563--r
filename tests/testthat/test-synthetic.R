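test_that("simulate_series implements the forward model", {
  tp <- hours48
  flat <- simulate_series(tibble::tibble(), mean = 5, noise_sd = 0, timepoints = tp)
  expect_equal(flat$value, rep(5, length(tp)))
  comp <- tibble::tibble(period = 12, decay = 1, amplitude = 3, peak_time = 0)
  s <- simulate_series(comp, mean = 0, noise_sd = 0, timepoints = tp)
  expect_equal(s$value[s$time == 0], 3)
  expect_equal(s$value[s$time == 6], -3)
  # determinism under a fixed seed
  a <- simulate_series(comp, 2, 0.5, tp, replicates = 2, seed = 99)
  b <- simulate_series(comp, 2, 0.5, tp, replicates = 2, seed = 99)
  expect_identical(a, b)
  expect_error(
    simulate_series(comp, 2, 0.1, c(0, 2, 5)),
    "uniformly spaced"
  )
})

test_that("synthetic_spec validates fractions and factors", {
  expect_error(
    synthetic_spec(10, class_fractions = c(
      null = 0.5, circadian = 0.4, twelvehour = 0, mixed = 0,
      eighthour = 0, subthreshold = 0
    )),
    "sum to 1"
  )
  expect_error(synthetic_spec(10, dampen_factor = 1.2), "not dampening")
  expect_error(synthetic_spec(0), "at least 1")
  # the published effect split sums to 1 and is accepted
  sp <- synthetic_spec(10, effect_fractions = c(
    abolished = 0.545, dampened = 0.316, increased = 0.139, unchanged = 0
  ))
  expect_s3_class(sp, "synthetic_spec")
})

test_that("cohorts honour class fractions and ground-truth invariants", {
  null_only <- c(
    null = 1, circadian = 0, twelvehour = 0, mixed = 0,
    eighthour = 0, subthreshold = 0
  )
  coh <- simulate_cohort(synthetic_spec(100, class_fractions = null_only, seed = 2))
  expect_true(all(is.na(coh$truth$period)))
  expect_equal(dplyr::n_distinct(coh$truth$gene), 100)

  tw_only <- c(
    null = 0, circadian = 0, twelvehour = 1, mixed = 0,
    eighthour = 0, subthreshold = 0
  )
  spec <- synthetic_spec(150, class_fractions = tw_only, seed = 3)
  coh <- simulate_cohort(spec)
  expect_true(all(
    coh$truth$period >= spec$twelvehour_period[1] &
      coh$truth$period <= spec$twelvehour_period[2]
  ))
  # every non-null gene has at least one component
  expect_true(all(!is.na(coh$truth$period)))

  # class fractions within binomial sampling error (4 sd)
  spec <- synthetic_spec(2000, seed = 4)
  coh <- simulate_cohort(spec)
  freq <- table(dplyr::distinct(coh$truth, gene, class)$class) / 2000
  for (cl in names(spec$class_fractions)) {
    p <- spec$class_fractions[[cl]]
    expect_lt(abs(freq[[cl]] - p), 4 * sqrt(p * (1 - p) / 2000) + 1e-12)
  }
  # sub-threshold genes sit below the background cut
  sub <- dplyr::filter(coh$truth, class == "subthreshold")
  expect_true(all(sub$baseline < 0.1))
})

test_that("cohort generation is deterministic given the seed", {
  a <- simulate_cohort(synthetic_spec(50, seed = 7))
  b <- simulate_cohort(synthetic_spec(50, seed = 7))
  expect_identical(a, b)
  c <- simulate_cohort(synthetic_spec(50, seed = 8))
  expect_false(identical(a$expression$value, c$expression$value))
})

test_that("two-condition truth applies 12-h effects exactly", {
  spec <- synthetic_spec(300, seed = 5)
  two <- simulate_two_conditions(spec)
  lo <- spec$twelvehour_period[1]
  hi <- spec$twelvehour_period[2]
  is12 <- !is.na(two$truth$period) & two$truth$period >= lo & two$truth$period <= hi
  ab <- two$truth$effect == "abolished" & is12
  expect_true(all(two$truth$amplitude_b[ab] == 0))
  da <- two$truth$effect == "dampened" & is12
  expect_equal(
    two$truth$amplitude_b[da],
    two$truth$amplitude[da] * spec$dampen_factor
  )
  inc <- two$truth$effect == "increased" & is12
  expect_equal(
    two$truth$amplitude_b[inc],
    two$truth$amplitude[inc] * spec$boost_factor
  )
  # non-12h components untouched
  expect_equal(two$truth$amplitude_b[!is12], two$truth$amplitude[!is12])
  # effect labels partition the genes; genes without a 12-h component are unchanged
  gene_eff <- dplyr::distinct(two$truth, gene, effect)
  expect_equal(nrow(gene_eff), 300)
  no12 <- !two$truth$gene %in% two$truth$gene[is12]
  expect_true(all(gene_eff$effect[match(
    unique(two$truth$gene[no12]), gene_eff$gene
  )] == "unchanged"))
})

test_that("unchanged genes differ between conditions only by noise", {
  spec <- synthetic_spec(40,
    effect_fractions = c(abolished = 0, dampened = 0, increased = 0, unchanged = 1),
    noise_frac = 0, seed = 6
  )
  two <- simulate_two_conditions(spec)
  expect_equal(two$expression_a$value, two$expression_b$value, tolerance = 1e-12)
})

test_that("coverage profile simulation produces recorded plateaus", {
  pr <- simulate_coverage_profile(2, 1, 50, 100, noise_sd = 0)
  expect_equal(nrow(pr), 150)
  expect_equal(unique(pr$value[1:50]), 2)
  expect_equal(unique(pr$value[51:150]), 1)
  expect_equal(attr(pr, "boundary"), 50)
  a <- simulate_coverage_profile(2, 1, 10, 20, noise_sd = 0.3, seed = 5)
  b <- simulate_coverage_profile(2, 1, 10, 20, noise_sd = 0.3, seed = 5)
  expect_identical(a$value, b$value)
  expect_error(simulate_coverage_profile(2, 1, 50, 0), "positive")
  expect_error(simulate_coverage_profile(-1, 1, 5, 5), "non-negative")
})
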