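test_that("paired circular mean difference wraps and signs correctly", {
  a <- c(g1 = 1, g2 = 5, g3 = 11)
  expect_equal(circular_mean_difference(a, a + 0.5, period = 12, paired = TRUE), 0.5)
  expect_equal(circular_mean_difference(a, a, period = 12, paired = TRUE), 0)
  # wrap-around: 11.9 h -> 0.1 h on a 12-h circle is a +0.2 h delay
  expect_equal(
    circular_mean_difference(c(g = 11.9), c(g = 0.1), period = 12, paired = TRUE),
    0.2
  )
  # antisymmetry
  b <- c(g1 = 2, g2 = 4.5, g3 = 0.3)
  expect_equal(
    circular_mean_difference(a, b, period = 12, paired = TRUE),
    -circular_mean_difference(b, a, period = 12, paired = TRUE)
  )
  expect_error(
    circular_mean_difference(c(g1 = 1), c(g2 = 1), period = 12, paired = TRUE),
    "same gene names"
  )
})

test_that("unpaired mode compares group circular means", {
  a <- c(1, 1.2, 0.8)
  expect_equal(circular_mean_difference(a, a + 1, period = 12), 1,
    tolerance = 1e-9
  )
})

test_that("polar histogram bins are half-open and conserve counts", {
  h <- polar_histogram(rep(0.5, 10), period = 12, n_bins = 12)
  expect_equal(h$count[1], 10)
  expect_equal(sum(h$count), 10)
  withr::with_seed(31, ph <- runif(200, 0, 12))
  expect_equal(sum(polar_histogram(ph, 12, 8)$count), 200)
  # a phase exactly at a bin edge goes into the right-hand bin
  edge <- polar_histogram(c(1), period = 12, n_bins = 12)
  expect_equal(edge$count[2], 1)
  expect_equal(edge$lo[2], 1)
  expect_error(polar_histogram(1, 12, n_bins = 1), "at least 2")
})

test_that("Watson-Wheeler statistic matches a hand computation", {
  # two groups of 4 occupying ranks 1-4 and 5-8 of 8
  ph <- (1:8) / 8 * 12 # evenly spread, ranks equal positions
  g <- rep(c("a", "b"), each = 4)
  ww <- suppressWarnings(watson_wheeler_test(ph, g, period = 12))
  beta <- 2 * pi * (1:8) / 8
  Ca <- sum(cos(beta[1:4]))
  Sa <- sum(sin(beta[1:4]))
  Cb <- sum(cos(beta[5:8]))
  Sb <- sum(sin(beta[5:8]))
  W_hand <- 2 * ((Ca^2 + Sa^2) / 4 + (Cb^2 + Sb^2) / 4)
  expect_equal(unname(ww$statistic), W_hand, tolerance = 1e-12)
  expect_equal(unname(ww$parameter), 2)
  # exhaustive-permutation oracle over all 70 splits: contiguous ranks are
  # among the most extreme configurations (8 of the 70 splits tie at this W:
  # the 4 grid rotations of the block and their complements)
  expect_lte(ww_permutation_p(ph, g, 12), 8 / 70 + 1e-9)
})

test_that("Watson-Wheeler is rotation-invariant and null for interleaving", {
  withr::with_seed(32, ph <- runif(40, 0, 12))
  g <- rep(c("a", "b"), 20)
  w1 <- watson_wheeler_test(ph, g, 12)
  w2 <- watson_wheeler_test((ph + 3.7) %% 12, g, 12)
  expect_equal(unname(w1$statistic), unname(w2$statistic), tolerance = 1e-9)
  # perfectly interleaved groups on a uniform grid: no difference
  grid <- (1:40) * 12 / 40
  wi <- watson_wheeler_test(grid, rep(c("a", "b"), 20), 12)
  expect_lt(unname(wi$statistic), 1)
  expect_gt(wi$p.value, 0.5)
})

test_that("Watson-Wheeler warns on ties and small groups, rejects empties", {
  expect_warning(
    watson_wheeler_test(c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 2, 2, 3, 4, 5, 6),
      rep(c("a", "b"), each = 10),
      period = 24
    ),
    "midranks"
  )
  expect_warning(
    watson_wheeler_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), 3), 12),
    "below 10"
  )
  expect_error(
    watson_wheeler_test(c(1, 2), factor(c("a", "a"), levels = c("a", "b")), 12),
    "empty"
  )
})

test_that("Watson-Wheeler type-I error is near nominal", {
  withr::with_seed(33, {
    rej <- mean(replicate(500, {
      watson_wheeler_test(runif(60, 0, 12), rep(c("a", "b"), each = 30), 12)$p.value < 0.05
    }))
  })
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("progressive delay reports adjacent differences and monotone flag", {
  withr::with_seed(34, {
    base <- runif(40, 0, 0.5)
    df <- tibble::tibble(
      phase = c(base + 1, base + 1.5, base + 2),
      group = rep(c("mrna", "er", "golgi"), each = 40)
    )
  })
  out <- progressive_delay(df, order = c("mrna", "er", "golgi"), period = 12)
  expect_equal(out$mean_difference, c(0.5, 0.5), tolerance = 1e-9)
  expect_true(attr(out, "monotone_delay"))
  # reversing the order flips the signs
  rev_out <- progressive_delay(df, order = c("golgi", "er", "mrna"), period = 12)
  expect_equal(rev_out$mean_difference, c(-0.5, -0.5), tolerance = 1e-9)
  expect_false(attr(rev_out, "monotone_delay"))
  # identical groups: zero differences, flag off
  same <- tibble::tibble(
    phase = rep(base, 2),
    group = rep(c("x", "y"), each = 40)
  )
  out0 <- progressive_delay(same, order = c("x", "y"), period = 12)
  expect_equal(out0$mean_difference, 0, tolerance = 1e-9)
  expect_false(attr(out0, "monotone_delay"))
  expect_error(progressive_delay(df, order = "mrna"), "at least two")
})
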