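test_that("proportions are counted per level and pool across participants", {
  trials <- dplyr::bind_rows(
    make_trials(c(498, 600, 723), n_same = c(3, 12, 4), n_total = c(6, 18, 6)),
    make_trials(c(498, 600, 723),
      n_same = c(2, 10, 3), n_total = c(6, 18, 6),
      participant = "P02"
    )
  )
  agg <- aggregate_proportions(trials, phase = "T1")
  expect_equal(agg$level, c(498, 600, 723))
  expect_equal(agg$p_same[agg$level == 600], 22 / 36)

  per <- aggregate_proportions(trials, grouping = "per_participant")
  expect_identical(length(unique(per$participant_id)), 2L)
  expect_equal(per$p_same[per$participant_id == "P01" & per$level == 600], 12 / 18)
  # pooled counts equal the sum of per-participant counts
  expect_equal(
    agg$n_same,
    tapply(per$n_same, per$level, sum, default = 0)[as.character(agg$level)],
    ignore_attr = TRUE
  )
  expect_error(
    aggregate_proportions(trials, phase = "NOPE"),
    class = "samediff_empty_input"
  )
})

test_that("noise-free Gaussian samples are recovered to optimizer precision", {
  x <- duration_stimuli()$tests
  truth <- c(A = 0.8, mu = log10(600), sigma = 0.1)
  p <- truth["A"] * exp(-(log10(x) - truth["mu"])^2 / (2 * truth["sigma"]^2))
  fit <- fit_gaussian(tibble::tibble(level = x, p_same = p))
  expect_true(fit$converged)
  expect_equal(fit$amplitude, unname(truth["A"]), tolerance = 1e-6)
  expect_equal(fit$mu, unname(truth["mu"]), tolerance = 1e-6)
  expect_equal(fit$sigma, unname(truth["sigma"]), tolerance = 1e-6)
  expect_equal(fit$pse, 600, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fitting the generative curve recovers the gain-shifted peak", {
  x <- duration_stimuli()$tests
  p <- analytic_p_same(x, 600, observer_params(), "RUN_TEST")
  fit <- fit_gaussian(tibble::tibble(level = x, p_same = p))
  expect_true(fit$converged)
  expect_lt(abs(fit$pse - 513) / 513, 0.01) # within 1% of reference/gain
})

test_that("the fit equals a dense grid-search oracle on noise-free data", {
  x <- duration_stimuli()$tests
  lx <- log10(x)
  p <- 0.85 * exp(-(lx - log10(560))^2 / (2 * 0.12^2))
  fit <- fit_gaussian(tibble::tibble(level = x, p_same = p))

  grid_a <- seq(0.5, 1, by = 0.01)
  grid_mu <- seq(log10(450), log10(750), length.out = 121)
  grid_s <- seq(0.04, 0.25, by = 0.003)
  best <- c(Inf, NA, NA, NA)
  for (a in grid_a) {
    for (m in grid_mu) {
      ss <- vapply(
        grid_s,
        function(s) sum((p - a * exp(-(lx - m)^2 / (2 * s^2)))^2),
        0
      )
      i <- which.min(ss)
      if (ss[i] < best[1]) best <- c(ss[i], a, m, grid_s[i])
    }
  }
  expect_lt(abs(fit$amplitude - best[2]), 0.011)
  expect_lt(abs(fit$mu - best[3]), diff(grid_mu[1:2]) + 1e-9)
  expect_lt(abs(fit$sigma - best[4]), 0.0031)
})

test_that("degenerate inputs are flagged, not silently fitted", {
  x <- duration_stimuli()$tests
  expect_warning(
    flat <- fit_gaussian(tibble::tibble(level = x, p_same = rep(0.4, 9))),
    "did not converge"
  )
  expect_false(flat$converged)
  expect_true(is.na(flat$pse))
  expect_error(
    fit_gaussian(tibble::tibble(level = x[1:3], p_same = c(0.2, 0.8, 0.3))),
    class = "samediff_insufficient_data"
  )
})

test_that("Weber fractions are invariant to the log base", {
  s10 <- log10(1.3)
  expect_equal(weber_fraction(s10, 10), 0.3, tolerance = 1e-12)
  # natural-log width, exponentiated in base e, gives the same fraction
  se <- s10 * log(10)
  expect_equal(weber_fraction(se, exp(1)), weber_fraction(s10, 10), tolerance = 1e-12)
  expect_lt(weber_fraction(1e-9, 10), 1e-8) # Wf -> 0 with vanishing width
  expect_error(weber_fraction(0), class = "samediff_invalid_argument")
  expect_error(weber_fraction(0.1, 1), class = "samediff_invalid_argument")
})

test_that("the JND-over-PSE variant matches the antilog form to second order", {
  x <- duration_stimuli()$tests
  p <- 0.9 * exp(-(log10(x) - log10(600))^2 / (2 * 0.08^2))
  fit <- fit_gaussian(tibble::tibble(level = x, p_same = p))
  expect_equal(weber_fraction_jnd(fit), sinh(fit$sigma * log(10)), tolerance = 1e-9)
  expect_lt(abs(weber_fraction_jnd(fit) - fit$weber_fraction), 0.02)
})

test_that("scaling all magnitudes scales the PSE and nothing else", {
  x <- duration_stimuli()$tests
  withr::with_seed(5, p <- pmin(1, pmax(
    0,
    0.85 * exp(-(log10(x) - log10(570))^2 / (2 * 0.11^2)) + rnorm(9, 0, 0.02)
  )))
  f1 <- fit_gaussian(tibble::tibble(level = x, p_same = p))
  k <- 3.7
  f2 <- fit_gaussian(tibble::tibble(level = k * x, p_same = p))
  expect_equal(f2$pse, k * f1$pse, tolerance = 1e-5)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-6)
  expect_equal(f2$weber_fraction, f1$weber_fraction, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-9)
})

test_that("bias is the signed percent deviation of PSE from reference", {
  expect_equal(bias_percent(600, 600), 0)
  expect_equal(bias_percent(600, 513), 14.5)
  expect_equal(bias_percent(24, 30), -25)
})

test_that("single-phase fits recover the generative PSE across replicates", {
  op <- observer_params()
  sched <- build_decoding_schedule(duration_stimuli(), seed = 1)
  seeds <- withr::with_seed(99, sample.int(1e6, 100))
  pses <- vapply(seeds, function(s) {
    tr <- simulate_trials(sched, 600, op, phase = "RUN_TEST", seed = s)
    tr$participant_id <- "P01"
    tr$experiment_kind <- "duration_while"
    tr$block <- 1L
    fit <- suppressWarnings(fit_gaussian(aggregate_proportions(tr)))
    if (fit$converged) fit$pse else NA_real_
  }, 0)
  pses <- pses[!is.na(pses)]
  expect_gt(length(pses), 90)
  # median of 66-trial fits sits inside the Monte-Carlo CI of reference/gain
  mc_ci <- 1.96 * sd(pses) / sqrt(length(pses))
  expect_lt(abs(median(pses) - 513), 3 * mc_ci)
})

test_that("recovery bias vanishes at large trial counts", {
  op <- observer_params()
  sched <- build_decoding_schedule(duration_stimuli(),
    reps_nonreference = 1000, reps_reference = 3000, seed = 2
  ) # 11,000 trials
  tr <- simulate_trials(sched, 600, op, phase = "RUN_TEST", seed = 7)
  fit <- fit_gaussian(tibble::tibble(
    level = sort(unique(tr$test_magnitude)),
    p_same = tapply(tr$response == "same", tr$test_magnitude, mean)
  ))
  expect_lt(abs(fit$pse - 513) / 513, 0.01)
})

test_that("fit tables cover every participant-phase cell", {
  fits <- fit_table(fix_trials, grouping = "aggregate")
  expect_identical(nrow(fits), 3L)
  expect_true(all(fits$participant_id == "AGGREGATE"))
  expect_true(all(fits$converged))
  expect_true(all(fits$r_squared > 0.9))
  per <- fit_table(fix_trials, grouping = "per_participant")
  expect_identical(nrow(per), 45L)
  expect_identical(
    names(per),
    c(
      "participant_id", "experiment_kind", "phase", "A", "mu", "sigma",
      "pse", "weber_fraction", "bias_percent", "r_squared", "converged"
    )
  )
})
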