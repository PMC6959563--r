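test_that("constant series decomposes to its mean with no components", {
  d <- pencil_decompose(rep(5, 24), dt = 2)
  expect_equal(d$mean, 5)
  expect_equal(nrow(d$components), 0)
  expect_equal(d$residual_rms, 0)
})

test_that("a pure sustained 12-h cosine is recovered exactly", {
  x <- 3 * cos(2 * pi * hours48 / 12)
  d <- pencil_decompose(x, dt = 2)
  expect_equal(nrow(d$components), 1)
  expect_equal(d$components$period, 12, tolerance = 1e-6)
  expect_equal(d$components$decay, 1, tolerance = 1e-6)
  expect_equal(d$components$amplitude, 3, tolerance = 1e-6)
  expect_equal(d$components$peak_time, 0, tolerance = 1e-6)
})

test_that("two superimposed damped components are recovered to 1e-6", {
  x <- 2 * 0.9^(hours48 / 24) * cos(2 * pi * hours48 / 24 - pi / 2) +
    1 * 1.1^(hours48 / 12) * cos(2 * pi * hours48 / 12)
  d <- pencil_decompose(x, dt = 2)
  tr <- list(
    period = c(24, 12), decay = c(0.9, 1.1),
    amplitude = c(2, 1), peak = c(6, 0)
  )
  expect_lt(recovery_error(d$components, tr), 1e-6)
})

test_that("random noiseless 1-3 component signals are recovered to 1e-6", {
  withr::with_seed(101, {
    for (i in 1:60) {
      tr <- random_truth()
      x <- oracle_series(hours48, runif(1, 0, 10), tr$period, tr$decay,
        tr$amplitude, tr$peak
      )
      d <- pencil_decompose(x, dt = 2)
      expect_lt(recovery_error(d$components, tr), 1e-6)
    }
  })
})

test_that("decomposition is scale-equivariant and shift-covariant", {
  withr::with_seed(7, {
    tr <- random_truth(2)
    x <- oracle_series(hours48, 4, tr$period, tr$decay, tr$amplitude, tr$peak)
  })
  d1 <- pencil_decompose(x, dt = 2)
  d2 <- pencil_decompose(3 * x, dt = 2)
  expect_equal(d2$components$period, d1$components$period, tolerance = 1e-8)
  expect_equal(d2$components$decay, d1$components$decay, tolerance = 1e-8)
  expect_equal(d2$components$amplitude, 3 * d1$components$amplitude,
    tolerance = 1e-8
  )
  expect_equal(d2$components$peak_time, d1$components$peak_time,
    tolerance = 1e-8
  )
  # shifting the start by one sample rotates each phase by 2 pi dt / T
  xs <- oracle_series(hours48 + 2, 4, tr$period, tr$decay, tr$amplitude, tr$peak)
  ds <- pencil_decompose(xs, dt = 2)
  dphi <- (ds$components$phase - d1$components$phase) %% (2 * pi)
  expect_equal(dphi, (2 * pi * 2 / d1$components$period) %% (2 * pi),
    tolerance = 1e-6
  )
  expect_equal(ds$components$period, d1$components$period, tolerance = 1e-6)
})

test_that("reconstruction round-trips and subsets behave", {
  x <- 5 + 3 * cos(2 * pi * hours48 / 12) + 2 * cos(2 * pi * hours48 / 24)
  d <- pencil_decompose(x, dt = 2)
  expect_equal(pencil_reconstruct(d, hours48), x, tolerance = 1e-8)
  expect_equal(
    pencil_reconstruct(d, hours48, include = integer(0)),
    rep(d$mean, length(hours48))
  )
  expect_error(pencil_reconstruct(d, hours48, include = 99), "unknown component")
})

test_that("removing a period window leaves the other components", {
  x12 <- 3 * cos(2 * pi * hours48 / 12)
  x <- 5 + 2 * cos(2 * pi * hours48 / 24 - 1) + x12
  d <- pencil_decompose(x, dt = 2)
  resid <- remove_components(x, d, c(21, 25))
  expect_equal(resid - 5, x12, tolerance = 1e-6)
  # a window hitting nothing changes nothing
  d12 <- pencil_decompose(x12, dt = 2)
  expect_equal(remove_components(x12, d12, c(21, 25)), x12, tolerance = 1e-8)
  # removing everything leaves mean + residual
  all_gone <- remove_components(x, d, c(0, Inf))
  expect_equal(all_gone, rep(d$mean, length(hours48)), tolerance = 1e-8)
  expect_error(remove_components(x, d, c(25, 21)), "low <= high")
})

test_that("biological phase maps the cosine convention to peak hours", {
  expect_equal(biological_phase(0, 12), 0)
  expect_equal(biological_phase(pi, 12), 6)
  expect_equal(biological_phase(pi / 2, 12), 9)
  expect_true(all(biological_phase(seq(0, 6, by = 0.1), 12) >= 0))
  expect_true(all(biological_phase(seq(0, 6, by = 0.1), 12) < 12))
})

test_that("invalid series are rejected with informative errors", {
  expect_error(pencil_decompose(rep(1, 10), dt = 2), "too short")
  expect_error(
    decompose_genes(make_expression(list(g1 = c(1, 2, 3)), times = c(0, 2, 5))),
    "uniformly spaced"
  )
  expect_error(pencil_decompose(c(rep(1, 23), NA), dt = 2), "finite")
})

test_that("tidy and glance expose the component table and fit summary", {
  x <- 5 + 3 * cos(2 * pi * hours48 / 12)
  d <- pencil_decompose(x, dt = 2)
  expect_identical(tidy(d), d$components)
  g <- glance(d)
  expect_equal(g$n_components, 1L)
  expect_equal(g$mean, 5, tolerance = 1e-8)
  expect_equal(g$L, 12L)
})

test_that("per-sample decay convention reports the pole magnitude", {
  x <- 2 * 0.9^(hours48 / 24) * cos(2 * pi * hours48 / 24)
  d <- pencil_decompose(x, dt = 2, decay_per = "sample")
  expect_equal(d$components$decay, 0.9^(2 / 24), tolerance = 1e-6)
})

test_that("decompose_genes stacks per-gene components and flags constants", {
  df <- make_expression(list(
    flat = rep(2, 24),
    osc = 5 + cos(2 * pi * hours48 / 12)
  ))
  comps <- decompose_genes(df)
  expect_setequal(unique(comps$gene), c("flat", "osc"))
  flat <- dplyr::filter(comps, gene == "flat")
  expect_equal(flat$n_components, 0L)
  expect_true(is.na(flat$period))
  osc <- dplyr::filter(comps, gene == "osc")
  expect_equal(osc$period, 12, tolerance = 1e-6)
  expect_equal(osc$relative_amplitude, 1 / 5, tolerance = 1e-6)
})
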