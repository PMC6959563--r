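crit12 <- criteria_preset("liver_12h")

test_that("categories follow the matched/relative-amplitude rules", {
  a <- dplyr::bind_rows(
    component_row("g1", mean = 5, period = 12, amplitude = 1), # -> abolished
    component_row("g2", mean = 5, period = 12, amplitude = 1), # -> dampened
    component_row("g3", mean = 5, period = 12, amplitude = 1), # -> increased
    component_row("g4", mean = 5, period = 24, amplitude = 1), # no 12h either side
    component_row("g5", mean = 5, period = 12, amplitude = 1) # -> unchanged (tie)
  )
  b <- dplyr::bind_rows(
    component_row("g1", mean = 5, period = 24, amplitude = 1),
    component_row("g2", mean = 5, period = 12, amplitude = 0.5),
    component_row("g3", mean = 5, period = 12, amplitude = 2),
    component_row("g4", mean = 5, period = 12, amplitude = 1), # -> gained
    component_row("g5", mean = 5, period = 12, amplitude = 1)
  )
  del <- categorize_rhythms(a, b, crit12)
  expect_equal(
    del$category[match(c("g1", "g2", "g3", "g4", "g5"), del$gene)],
    c("abolished", "dampened", "increased", "gained", "unchanged")
  )
  # baseline shifts alone do not create dampened/increased labels: relative
  # amplitude is compared
  a2 <- component_row("h", mean = 5, period = 12, amplitude = 1)
  b2 <- component_row("h", mean = 10, period = 12, amplitude = 2)
  expect_equal(categorize_rhythms(a2, b2, crit12)$category, "unchanged")
})

test_that("categorization is antisymmetric under condition swap", {
  withr::with_seed(51, {
    two <- simulate_two_conditions(synthetic_spec(150, noise_frac = 0, seed = 51))
  })
  ca <- decompose_genes(average_replicates(two$expression_a))
  cb <- decompose_genes(average_replicates(two$expression_b))
  ab <- categorize_rhythms(ca, cb, crit12)
  ba <- categorize_rhythms(cb, ca, crit12)
  swap <- c(
    abolished = "gained", gained = "abolished", dampened = "increased",
    increased = "dampened", unchanged = "unchanged"
  )
  m <- dplyr::inner_join(ab, ba, by = "gene", suffix = c("_ab", "_ba"))
  expect_equal(nrow(m), nrow(ab))
  expect_equal(unname(swap[m$category_ab]), m$category_ba)
})

test_that("noise-free two-condition categorization recovers effect labels", {
  spec <- synthetic_spec(400, noise_frac = 0, seed = 52)
  two <- simulate_two_conditions(spec)
  ca <- decompose_genes(average_replicates(two$expression_a))
  cb <- decompose_genes(average_replicates(two$expression_b))
  del <- categorize_rhythms(ca, cb, crit12)
  truth <- two$truth |>
    dplyr::filter(.data$effect != "unchanged", .data$class != "subthreshold") |>
    dplyr::distinct(.data$gene, .data$effect)
  m <- dplyr::inner_join(del, truth, by = "gene")
  expect_equal(nrow(m), nrow(truth)) # every affected expressed gene found
  expect_equal(m$category, m$effect)
})

test_that("cohort summary reports counts, exact ratios, and percentages", {
  deltas <- tibble::tibble(category = rep(
    c("abolished", "dampened", "increased"),
    c(2501, 1454, 639)
  ))
  s <- cohort_summary(deltas)
  expect_equal(sum(s$n), 4594)
  expect_equal(s$percent[s$category == "abolished"], 54.4)
  expect_equal(s$percent[s$category == "dampened"], 31.6)
  expect_equal(s$percent[s$category == "increased"], 13.9)
  expect_equal(s$fraction, s$n / 4594)
  expect_lt(abs(sum(s$percent) - 100), 0.2)
  one <- cohort_summary(tibble::tibble(category = "abolished"))
  expect_equal(one$percent, 100)
  expect_error(cohort_summary(tibble::tibble(category = character(0))), "non-empty")
})

test_that("overlap summary counts common and unique members", {
  expect_equal(
    overlap_summary(c("g1", "g2"), c("g2", "g3")),
    tibble::tibble(common = 1L, only_a = 1L, only_b = 1L)
  )
  expect_equal(
    overlap_summary(c("a", "b", "b"), c("a", "b")),
    tibble::tibble(common = 2L, only_a = 0L, only_b = 0L)
  )
  expect_equal(
    overlap_summary(c("a"), c("b", "c")),
    tibble::tibble(common = 0L, only_a = 1L, only_b = 2L)
  )
})

test_that("harmonic period-lock products match the published arithmetic", {
  l1 <- harmonic_lock_ratio(7.3, 21.6)
  expect_equal(l1$k, 3L)
  expect_equal(l1$implied_period, 21.9)
  l2 <- harmonic_lock_ratio(10.8, 21.6)
  expect_equal(l2$k, 2L)
  expect_equal(l2$implied_period, 21.6)
  expect_true(l2$locked)
  l3 <- harmonic_lock_ratio(12, 24)
  expect_equal(l3$k, 2L)
  expect_true(l3$locked)
  expect_error(harmonic_lock_ratio(-1, 24), "positive")
})
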