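test_that("the bootstrap Z formula reproduces hand-computed values", {
  z <- z_compare(c(513.2, 6.7), c(588.4, 7.6))
  expect_equal(z$statistic, 7.42, tolerance = 0.001)
  expect_lt(z$p_value, 1e-10)

  expect_equal(z_compare(c(0, 3), c(3, 4))$statistic, 0.6, tolerance = 1e-12)

  same <- z_compare(c(500, 5), c(500, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # symmetric in its arguments
  a <- c(513.2, 6.7)
  b <- c(588.4, 7.6)
  expect_equal(z_compare(a, b)$statistic, z_compare(b, a)$statistic)
  expect_error(z_compare(c(1, 0), c(2, 0)), class = "samediff_invalid_argument")
})

test_that("Bonferroni thresholds divide alpha by the comparison count", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
  expect_lt(abs(bonferroni_alpha(0.05, 3) - 0.0167), 5e-4)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
})

test_that("JZS Bayes factors agree with an independent prior-integral oracle", {
  # oracle: average the noncentral-t likelihood over the Cauchy effect prior
  oracle <- function(t, n, r = 0.707) {
    nu <- n - 1
    num <- integrate(
      function(d) suppressWarnings(dt(t, nu, ncp = d * sqrt(n))) * dcauchy(d, 0, r),
      -Inf, Inf,
      rel.tol = 1e-10
    )$value
    log10(num / dt(t, nu))
  }
  for (case in list(c(0.21, 15), c(2.5, 10), c(7.27, 15), c(-1.3, 8))) {
    expect_equal(
      jzs_log10_bf(case[1], case[2]),
      oracle(case[1], case[2]),
      tolerance = 1e-6
    )
  }
})

test_that("Bayes factors favor the null at t = 0 and grow with |t|", {
  for (n in c(5, 15, 40)) {
    expect_lt(jzs_log10_bf(0, n), 0) # BF10 < 1 at t = 0
  }
  ts <- c(0, 0.5, 1, 2, 4, 8)
  bfs <- vapply(ts, jzs_log10_bf, 0, n = 15)
  expect_true(all(diff(bfs) > 0))
  # symmetric in the sign of t
  expect_equal(jzs_log10_bf(-2, 12), jzs_log10_bf(2, 12))
})

test_that("bootstrap peak distributions are deterministic and centered", {
  run <- fix_trials[fix_trials$phase == "RUN_TEST", ]
  b1 <- bootstrap_pse(run, n_iterations = 300, seed = 17)
  b2 <- bootstrap_pse(run, n_iterations = 300, seed = 17)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$n_failed, 0L)
  # centering: bootstrap mean within 2 SEs of the point-estimate PSE
  expect_lt(abs(b1$mean_peak - b1$point_pse), 2 * b1$se_peak)
  # single-iteration structure
  b3 <- bootstrap_pse(run, n_iterations = 1, seed = 4)
  expect_length(b3$peaks, 1)
})

test_that("bootstrap spread shrinks as per-level counts grow", {
  op <- observer_params()
  make_agg <- function(reps_nonref, reps_ref, seed) {
    sched <- build_decoding_schedule(duration_stimuli(), reps_nonref, reps_ref, seed = seed)
    tr <- simulate_trials(sched, 600, op, phase = "RUN_TEST", seed = seed + 1)
    tr$participant_id <- "P01"
    tr$experiment_kind <- "duration_while"
    tr$block <- 1L
    tr
  }
  small <- bootstrap_pse(make_agg(6, 18, 31), n_iterations = 200, seed = 1)
  big <- bootstrap_pse(make_agg(96, 288, 32), n_iterations = 200, seed = 2)
  expect_lt(big$se_peak, small$se_peak / 2) # 16x the data, ~4x tighter
})

test_that("an unstable bootstrap raises its warning and records failures", {
  # six trials over four levels: resamples frequently drop below four levels
  tiny <- make_trials(c(498, 600, 723, 872),
    n_same = c(1, 1, 1, 0), n_total = c(2, 1, 2, 1)
  )
  expect_warning(
    b <- bootstrap_pse(tiny, n_iterations = 100, seed = 3),
    "Unstable bootstrap"
  )
  expect_gt(b$n_failed, 10)
  expect_true(b$unstable)
})

test_that("paired t contrasts handle degenerate and null inputs", {
  zero <- t_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$effect_size_d, 0)
  # a constant PSE ratio collapses the log differences to a nonzero constant
  expect_error(
    t_compare(c(2, 4, 6), c(1, 2, 3)),
    class = "samediff_degenerate_contrast"
  )
  expect_error(
    t_compare(c(5, 6, 7), c(4, 5, 6), log_units = FALSE),
    class = "samediff_degenerate_contrast"
  )
  expect_error(t_compare(1:4, 1:3), class = "samediff_invalid_argument")
})

test_that("the while-running gain is detected by the paired t in nearly every cohort", {
  plan <- build_session_plan("duration_while")
  op <- observer_params()
  seeds <- withr::with_seed(55, sample.int(1e6, 100))
  hits <- 0L
  for (s in seeds) {
    tr <- simulate_cohort(plan, cohort_params(15, seed = s), op)
    tr <- tr[tr$phase %in% c("RUN_TEST", "T1"), ]
    per <- fit_table(tr, grouping = "per_participant")
    per <- per[per$converged, ]
    run <- per[per$phase == "RUN_TEST", ]
    t1 <- per[per$phase == "T1", ]
    shared <- intersect(run$participant_id, t1$participant_id)
    res <- t_compare(
      run$pse[match(shared, run$participant_id)],
      t1$pse[match(shared, t1$participant_id)]
    )
    if (res$significant) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("median splits honor the tie rule and flag degenerate halves", {
  plan <- build_session_plan("duration_after", n_blocks = 1)
  tr <- simulate_cohort(plan, cohort_params(8, seed = 6))
  ms <- median_split_compare(tr,
    baseline_phase = "T1", test_phase = "TEST_AFTER",
    n_iterations = 100, seed = 2
  )
  expect_named(ms$split_times, c("T1", "TEST_AFTER"))
  expect_s3_class(ms$early$comparison, "comparison_result")
  expect_s3_class(ms$late$comparison, "comparison_result")
  expect_true(ms$early$baseline_fit$converged)
  # reproducible under the same seed
  ms2 <- median_split_compare(tr,
    baseline_phase = "T1", test_phase = "TEST_AFTER",
    n_iterations = 100, seed = 2
  )
  expect_identical(ms$early$comparison$statistic, ms2$early$comparison$statistic)

  # identical time stamps: every trial ties into the early half
  flat <- tr
  flat$seconds_since_phase_start <- 1
  expect_error(
    median_split_compare(flat, baseline_phase = "T1", test_phase = "TEST_AFTER"),
    class = "samediff_insufficient_data"
  )
})

test_that("median-split Z-tests stay null when no gain is present", {
  plan <- build_session_plan("duration_after", n_blocks = 1)
  op <- observer_params(gain_by_phase = c(TEST_AFTER = 1))
  seeds <- withr::with_seed(77, sample.int(1e6, 100))
  both_ns <- 0L
  for (s in seeds) {
    tr <- simulate_cohort(plan, cohort_params(8, seed = s), op)
    ms <- median_split_compare(tr,
      baseline_phase = "T1", test_phase = "TEST_AFTER",
      n_iterations = 100, seed = s, alpha = 0.05, comparisons = 3
    )
    if (!ms$early$comparison$significant && !ms$late$comparison$significant) {
      both_ns <- both_ns + 1L
    }
  }
  expect_gte(both_ns, 90)
})

test_that("precision correlations behave at the limits and under the null", {
  expect_equal(precision_correlation(1:5, 1:5)$statistic, 1, tolerance = 1e-12)
  expect_equal(precision_correlation(1:5, 5:1)$statistic, -1, tolerance = 1e-12)
  expect_error(
    precision_correlation(rep(0.2, 5), 1:5),
    class = "samediff_degenerate_contrast"
  )
  # independent Weber fractions rarely show |r| >= 0.5 at n = 15
  hits <- withr::with_seed(31, {
    sum(vapply(1:100, function(i) {
      wf_a <- exp(rnorm(15, log(0.25), 0.2))
      wf_b <- exp(rnorm(15, log(0.15), 0.2))
      abs(precision_correlation(wf_a, wf_b)$statistic) < 0.5
    }, TRUE))
  })
  expect_gte(hits, 90)
})
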