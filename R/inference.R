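#' Bootstrap distribution of the fitted psychometric peak
#'
#' Resamples trial rows with replacement (as many draws as the original
#' trial count), re-aggregates the per-level proportions, refits the
#' log-Gaussian and records its peak (the PSE), for `n_iterations`
#' repetitions. The refits start from the full-data point estimate (plus a
#' small bracket of widths), which keeps 10,000 iterations tractable;
#' non-converged iterations are counted and excluded, and more than 10%
#' failures raises an unstable-fit warning carried in the result.
#'
#' @param trials Canonical trial table (typically aggregate data for one
#'   phase).
#' @param phase Optional phase label to filter on.
#' @param n_iterations Bootstrap iterations (canonically 10,000).
#' @param seed Integer seed; identical seeds give identical peak lists.
#' @param weighted Passed to the refits.
#' @return A `bootstrap_pse`: `peaks` (one fitted PSE per successful
#'   iteration), `n_iterations`, `n_failed`, `mean_peak`, `se_peak` (the
#'   standard deviation of the peaks), `point_pse`, `seed`, `unstable`.
#' @export
bootstrap_pse <- function(trials, phase = NULL, n_iterations = 10000,
                          seed = 1, weighted = FALSE) {
  check_trial_table(trials)
  if (!is.null(phase)) trials <- trials[trials$phase %in% phase, ]
  if (nrow(trials) == 0) {
    rlang::abort("No trials to bootstrap.",
      class = c("samediff_empty_input", "samediff_error")
    )
  }
  n_iterations <- check_count(n_iterations, "n_iterations")

  point <- fit_gaussian(aggregate_proportions(trials), weighted = weighted)
  if (!point$converged) {
    abort_invalid("Point fit did not converge; cannot bootstrap.")
  }
  levels_all <- sort(unique(trials$test_magnitude))
  li <- match(trials$test_magnitude, levels_all)
  same <- trials$response == "same"
  n <- nrow(trials)
  nlev <- length(levels_all)
  # refit starts: the point estimate with one wider-width companion; the
  # polish pass is skipped since peak spread dwarfs optimizer granularity
  starts <- rbind(
    c(point$amplitude, point$mu, point$sigma),
    c(point$amplitude, point$mu, point$sigma * 1.6)
  )

  x_all <- log10(levels_all)
  peaks <- numeric(n_iterations)
  failed <- 0L
  withr::with_seed(as.integer(seed), {
    for (it in seq_len(n_iterations)) {
      idx <- sample.int(n, n, replace = TRUE)
      lidx <- li[idx]
      n_tot <- tabulate(lidx, nlev)
      n_same <- tabulate(lidx[same[idx]], nlev)
      keep <- n_tot > 0
      if (sum(keep) < 4) {
        failed <- failed + 1L
        peaks[it] <- NA_real_
        next
      }
      w <- if (weighted) n_tot[keep] else rep(1, sum(keep))
      core <- fit_gauss_core(x_all[keep], n_same[keep] / n_tot[keep], w, starts,
        polish = FALSE
      )
      fit <- core$fit
      ok <- !is.null(fit) && fit$convergence == 0 &&
        fit$par[3] < core$upper[3] - 1e-6 && fit$par[1] > core$lower[1] + 1e-6
      if (ok) {
        peaks[it] <- 10^fit$par[2]
      } else {
        failed <- failed + 1L
        peaks[it] <- NA_real_
      }
    }
  })
  peaks <- peaks[!is.na(peaks)]
  unstable <- failed > 0.1 * n_iterations
  if (unstable) {
    warning(
      sprintf(
        "Unstable bootstrap: %d of %d iterations failed to converge.",
        failed, n_iterations
      ),
      call. = FALSE
    )
  }
  structure(
    list(
      peaks = peaks, n_iterations = n_iterations, n_failed = failed,
      mean_peak = mean(peaks), se_peak = sd(peaks),
      point_pse = point$pse, seed = as.integer(seed), unstable = unstable
    ),
    class = "bootstrap_pse"
  )
}

#' @export
print.bootstrap_pse <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_pse> mean peak %.4g +/- %.3g (%d iterations, %d failed, seed %d)\n",
    x$mean_peak, x$se_peak, x$n_iterations, x$n_failed, x$seed
  ))
  invisible(x)
}

#' @noRd
comparison_result <- function(statistic_kind, statistic, p_value,
                              df = NA_real_, alpha = 0.05,
                              alpha_corrected = alpha,
                              effect_size_d = NA_real_,
                              log10_bf10 = NA_real_, extra = list()) {
  structure(
    c(
      list(
        statistic_kind = statistic_kind, statistic = statistic, df = df,
        p_value = p_value, alpha_corrected = alpha_corrected,
        effect_size_d = effect_size_d, log10_bf10 = log10_bf10,
        significant = p_value < alpha_corrected
      ),
      extra
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  lab <- switch(x$statistic_kind,
    bootstrap_z = sprintf("Z = %.3g", x$statistic),
    one_sample_t = ,
    paired_t = sprintf("t(%g) = %.3g", x$df, x$statistic),
    pearson_r = sprintf("r(%g) = %.3g", x$df, x$statistic),
    sprintf("stat = %.3g", x$statistic)
  )
  cat(sprintf(
    "<comparison_result> %s, p = %.3g (alpha = %.4g)%s%s%s\n",
    lab, x$p_value, x$alpha_corrected,
    if (!is.na(x$effect_size_d)) sprintf(", d = %.3g", x$effect_size_d) else "",
    if (!is.na(x$log10_bf10)) sprintf(", log10 BF10 = %.3g", x$log10_bf10) else "",
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' @noRd
as_mean_se <- function(x, name) {
  if (inherits(x, "bootstrap_pse")) {
    return(list(mean = x$mean_peak, se = x$se_peak))
  }
  if (is.list(x) && all(c("mean", "se") %in% names(x))) {
    return(list(mean = x$mean, se = x$se))
  }
  if (is.numeric(x) && length(x) == 2) {
    return(list(mean = x[1], se = x[2]))
  }
  abort_invalid(sprintf(
    "`%s` must be a bootstrap_pse, a list(mean=, se=), or c(mean, se).", name
  ))
}

#' Z-test between two bootstrap peak distributions
#'
#' The Z score is the distance between the distribution means divided by the
#' combined standard error, `|mean_a - mean_b| / sqrt(se_a^2 + se_b^2)`,
#' with a two-sided p-value from the standard normal. Symmetric in its
#' arguments.
#'
#' @param a,b [bootstrap_pse()] objects, or `list(mean =, se =)`, or
#'   length-2 vectors `c(mean, se)`.
#' @param alpha Uncorrected significance level.
#' @param comparisons Number of comparisons in the family; the threshold is
#'   Bonferroni-corrected to `alpha / comparisons`.
#' @return A `comparison_result` of kind `bootstrap_z`.
#' @examples
#' z_compare(c(513.2, 6.7), c(588.4, 7.6)) # Z = 7.42
#' @export
z_compare <- function(a, b, alpha = 0.05, comparisons = 1) {
  a <- as_mean_se(a, "a")
  b <- as_mean_se(b, "b")
  if (a$se < 0 || b$se < 0 || (a$se == 0 && b$se == 0)) {
    abort_invalid("Standard errors must be positive (combined variance > 0).")
  }
  z <- abs(a$mean - b$mean) / sqrt(a$se^2 + b$se^2)
  p <- 2 * pnorm(-z)
  comparison_result(
    "bootstrap_z", z, p,
    alpha = alpha,
    alpha_corrected = bonferroni_alpha(alpha, comparisons),
    extra = list(mean_a = a$mean, mean_b = b$mean, se_a = a$se, se_b = b$se)
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param k Number of comparisons.
#' @return `alpha / k` (0.05 over three comparisons gives 0.0167).
#' @export
bonferroni_alpha <- function(alpha = 0.05, k = 1) {
  k <- check_count(k, "k")
  if (alpha <= 0 || alpha > 1) abort_invalid("`alpha` must be in (0, 1].")
  alpha / k
}

#' Paired t-test between per-participant PSEs
#'
#' Tests condition-vs-baseline PSE differences across participants with a
#' paired t-test. Differences are taken in log10 units by default (the
#' scale on which individual PSEs scatter symmetrically); set
#' `log_units = FALSE` for linear units. Cohen's d is
#' `mean(diff) / sd(diff)`, and a default JZS Bayes factor
#' ([jzs_log10_bf()]) accompanies the t statistic.
#'
#' @param pse_condition,pse_baseline Paired per-participant PSE vectors
#'   (length >= 3).
#' @param log_units Compare log10 PSEs (default) or linear PSEs.
#' @param alpha,comparisons Significance threshold controls as in
#'   [z_compare()].
#' @param cauchy_scale Prior scale for the Bayes factor.
#' @return A `comparison_result` of kind `paired_t` with `df = n - 1`,
#'   Cohen's d and `log10_bf10`.
#' @export
t_compare <- function(pse_condition, pse_baseline, log_units = TRUE,
                      alpha = 0.05, comparisons = 1, cauchy_scale = 0.707) {
  n <- length(pse_condition)
  if (n != length(pse_baseline)) abort_invalid("PSE vectors must be paired.")
  if (n < 3) abort_invalid("At least 3 pairs are required.")
  d <- if (log_units) {
    log10(pse_condition) - log10(pse_baseline)
  } else {
    pse_condition - pse_baseline
  }
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(comparison_result(
        "paired_t", 0, 1,
        df = n - 1, alpha = alpha,
        alpha_corrected = bonferroni_alpha(alpha, comparisons),
        effect_size_d = 0,
        log10_bf10 = jzs_log10_bf(0, n, cauchy_scale)
      ))
    }
    rlang::abort(
      "Constant nonzero differences: t statistic is unbounded.",
      class = c("samediff_degenerate_contrast", "samediff_error")
    )
  }
  tt <- t.test(d, mu = 0)
  tstat <- unname(tt$statistic)
  comparison_result(
    "paired_t", tstat, tt$p.value,
    df = unname(tt$parameter),
    alpha = alpha, alpha_corrected = bonferroni_alpha(alpha, comparisons),
    effect_size_d = mean(d) / sd(d),
    log10_bf10 = jzs_log10_bf(tstat, n, cauchy_scale)
  )
}

#' Default JZS Bayes factor from a t statistic
#'
#' Computes the one-sample (equivalently paired-difference) default Bayes
#' factor for a t-design: a Cauchy prior with scale `cauchy_scale` on the
#' standardized effect size under the alternative, against a point null.
#' The Cauchy is represented as a normal scale mixture with an
#' inverse-gamma(1/2, scale^2/2) mixing density, and the Bayes factor is
#' obtained by numerical integration of the resulting one-dimensional
#' integral — a form that stays numerically stable for large t. Returns the
#' base-10 logarithm of BF10; negative values favor the null.
#'
#' @param t Observed t statistic (df = n - 1).
#' @param n Sample size (>= 2).
#' @param cauchy_scale Cauchy prior scale (default 0.707, the conventional
#'   sqrt(2)/2).
#' @return `log10(BF10)`.
#' @examples
#' jzs_log10_bf(7.27, 15) # ~ 3.7
#' jzs_log10_bf(0.21, 15) # ~ -0.57
#' @export
jzs_log10_bf <- function(t, n, cauchy_scale = 0.707) {
  n <- check_count(n, "n", min = 2L)
  cauchy_scale <- check_positive(cauchy_scale, "cauchy_scale")
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) {
    abort_invalid("`t` must be a single finite number.")
  }
  nu <- n - 1
  r2 <- cauchy_scale^2
  # BF10 = integral over g of the marginal-likelihood ratio times the
  # inverse-gamma mixing density; the ratio form avoids underflow.
  integrand <- function(g) {
    ratio <- (1 + t^2 / ((1 + n * g) * nu)) / (1 + t^2 / nu)
    (1 + n * g)^(-1 / 2) * ratio^(-(nu + 1) / 2) *
      sqrt(r2 / (2 * pi)) * g^(-3 / 2) * exp(-r2 / (2 * g))
  }
  bf <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = 1e-9, abs.tol = 0)$value,
    error = function(e) {
      rlang::abort(
        paste0("Bayes factor integration failed: ", conditionMessage(e)),
        class = c("samediff_numerical_failure", "samediff_error")
      )
    }
  )
  log10(bf)
}

#' Median-split early/late bootstrap comparison
#'
#' Splits the baseline and test trials (aggregated across participants) at
#' the median of the time elapsed since the end of the run, fits and
#' bootstraps each half independently, and Z-compares baseline against test
#' within each half. Trials exactly at the median go to the early half.
#'
#' @param trials Canonical trial table carrying
#'   `seconds_since_phase_start` time stamps.
#' @param baseline_phase,test_phase Phase labels to contrast.
#' @param n_iterations Bootstrap iterations per half and phase.
#' @param seed Root seed (split across the four bootstraps).
#' @param alpha,comparisons Threshold controls as in [z_compare()].
#' @return A `median_split` list with elements `early` and `late`, each
#'   holding `baseline_fit`, `test_fit` and a `comparison`
#'   (`comparison_result` of kind `bootstrap_z`), plus the split times.
#' @export
median_split_compare <- function(trials, baseline_phase = "T1",
                                 test_phase = "TEST_AFTER",
                                 n_iterations = 1000, seed = 1,
                                 alpha = 0.05, comparisons = 1) {
  check_trial_table(trials)
  seeds <- derive_seeds(seed, 4L)
  halves <- list()
  split_times <- list()
  for (half in c("early", "late")) {
    sub <- list()
    for (ph in c(baseline_phase, test_phase)) {
      tr <- trials[trials$phase == ph, ]
      if (nrow(tr) == 0) {
        rlang::abort(sprintf("No trials in phase '%s'.", ph),
          class = c("samediff_empty_input", "samediff_error")
        )
      }
      med <- median(tr$seconds_since_phase_start)
      split_times[[ph]] <- med
      pick <- if (half == "early") {
        tr$seconds_since_phase_start <= med # ties to the early half
      } else {
        tr$seconds_since_phase_start > med
      }
      tr <- tr[pick, ]
      if (length(unique(tr$test_magnitude)) < 4) {
        rlang::abort(
          sprintf(
            "The %s half of phase '%s' covers fewer than 4 levels (%d trials).",
            half, ph, nrow(tr)
          ),
          class = c("samediff_insufficient_data", "samediff_error")
        )
      }
      sub[[ph]] <- tr
    }
    si <- if (half == "early") 1:2 else 3:4
    boot_base <- bootstrap_pse(sub[[baseline_phase]],
      n_iterations = n_iterations, seed = seeds[si[1]]
    )
    boot_test <- bootstrap_pse(sub[[test_phase]],
      n_iterations = n_iterations, seed = seeds[si[2]]
    )
    halves[[half]] <- list(
      baseline_fit = fit_gaussian(aggregate_proportions(sub[[baseline_phase]])),
      test_fit = fit_gaussian(aggregate_proportions(sub[[test_phase]])),
      baseline_bootstrap = boot_base,
      test_bootstrap = boot_test,
      comparison = z_compare(boot_base, boot_test,
        alpha = alpha, comparisons = comparisons
      )
    )
  }
  structure(
    c(halves, list(split_times = split_times, seed = as.integer(seed))),
    class = "median_split"
  )
}

#' Pearson correlation between per-participant precision indices
#'
#' Correlates condition-averaged Weber fractions across two tasks (e.g.
#' duration vs numerosity) with a two-sided Pearson test.
#'
#' @param wf_a,wf_b Paired per-participant Weber fractions (length >= 3).
#' @param alpha Significance level.
#' @return A `comparison_result` of kind `pearson_r` with `statistic = r`
#'   and `df = n - 2`.
#' @export
precision_correlation <- function(wf_a, wf_b, alpha = 0.05) {
  n <- length(wf_a)
  if (n != length(wf_b)) abort_invalid("Weber-fraction vectors must be paired.")
  if (n < 3) abort_invalid("At least 3 pairs are required.")
  if (sd(wf_a) == 0 || sd(wf_b) == 0) {
    rlang::abort(
      "Zero variance in a precision vector: correlation undefined.",
      class = c("samediff_degenerate_contrast", "samediff_error")
    )
  }
  ct <- cor.test(wf_a, wf_b, method = "pearson")
  comparison_result(
    "pearson_r", unname(ct$estimate), ct$p.value,
    df = unname(ct$parameter), alpha = alpha, alpha_corrected = alpha
  )
}
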