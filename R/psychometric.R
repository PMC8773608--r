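#' Aggregate trial-level responses into per-level "same" proportions
#'
#' Counts "same" responses per test magnitude, either pooling every
#' participant's trials before counting (`"aggregate"`, the default) or
#' separately per participant.
#'
#' @param trials Canonical trial table (see [simulate_cohort()]).
#' @param grouping `"aggregate"` or `"per_participant"`.
#' @param phase Optional phase label (or vector of labels) to filter on.
#' @return For `"aggregate"`, a `level_proportions` tibble with columns
#'   `level`, `n_same`, `n_total`, `p_same` (levels strictly increasing).
#'   For `"per_participant"`, the same columns preceded by `participant_id`.
#' @export
aggregate_proportions <- function(trials,
                                  grouping = c("aggregate", "per_participant"),
                                  phase = NULL) {
  grouping <- match.arg(grouping)
  check_trial_table(trials)
  if (!is.null(phase)) trials <- trials[trials$phase %in% phase, ]
  if (nrow(trials) == 0) {
    rlang::abort(
      "No trials for the requested phase.",
      class = c("samediff_empty_input", "samediff_error")
    )
  }
  keys <- if (grouping == "per_participant") {
    c("participant_id", "test_magnitude")
  } else {
    "test_magnitude"
  }
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_same = sum(.data$response == "same"),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_same = .data$n_same / .data$n_total) |>
    dplyr::rename(level = "test_magnitude") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(
      if (grouping == "per_participant") c("participant_id", "level") else "level"
    )))
  class(out) <- c("level_proportions", class(out))
  attr(out, "grouping") <- grouping
  out
}

# Core least-squares engine: fits p = A * exp(-(x - mu)^2 / (2 sigma^2)) on
# x = log10(level) from a matrix of starting points (columns A, mu, sigma).
# Returns the best optim() result plus bookkeeping. Box bounds keep A in
# (0, 1] and sigma positive; sigma at its upper bound marks a degenerate
# (flat) solution. L-BFGS-B's code 52 (linesearch breakdown at machine
# precision, routine on near-zero-residual data) is treated as converged;
# the returned point is still a minimizer.
#' @noRd
fit_gauss_core <- function(x, y, w, starts, polish = TRUE) {
  lower <- c(1e-4, min(x) - 0.5, 1e-3)
  upper <- c(1, max(x) + 0.5, 2)
  obj <- function(par) {
    sum(w * (y - par[1] * exp(-(x - par[2])^2 / (2 * par[3]^2)))^2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[i, ], lower), upper), obj,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 1e7, pgtol = 1e-10, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best) && polish) {
    # polish from the winning start; ignore failures of the refinement pass
    refined <- tryCatch(
      optim(best$par, obj,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(factr = 10, pgtol = 1e-12, maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(refined) && refined$value <= best$value) {
      refined$convergence <- min(refined$convergence, best$convergence)
      best <- refined
    }
  }
  if (!is.null(best) && best$convergence == 52) best$convergence <- 0
  list(fit = best, lower = lower, upper = upper)
}

#' @noRd
default_starts <- function(x, y) {
  a0 <- min(max(max(y), 0.05), 1)
  as.matrix(expand.grid(A = a0, mu = x, sigma = c(0.05, 0.1, 0.2)))
}

#' Fit a Gaussian psychometric function on a log magnitude axis
#'
#' Least-squares fit of `p(x) = A * exp(-(log10(x) - mu)^2 / (2 sigma^2))`
#' to per-level proportions of "same" responses. The peak location gives the
#' point of subjective equality `PSE = 10^mu`; the width gives the Weber
#' fraction `10^sigma - 1`. Initialization is multistart (`mu` at every
#' observed level, `sigma` in {0.05, 0.1, 0.2} log10 units, `A` at the
#' maximum observed proportion); the lowest residual sum of squares wins,
#' with the deterministic start order breaking ties. Goodness of fit is
#' `R^2 = 1 - SS_res / SS_tot` on the proportions.
#'
#' Fits are unweighted by default, treating each level's proportion equally;
#' set `weighted = TRUE` to weight levels by their trial counts (relevant
#' when the reference level has three times the trials of the others).
#'
#' @param props A `level_proportions` table from [aggregate_proportions()]
#'   (aggregate grouping), or any data frame with columns `level`, `p_same`
#'   and optionally `n_total`.
#' @param weighted Weight squared errors by `n_total`.
#' @param starts Optional numeric matrix of starting points (columns A, mu,
#'   sigma) replacing the default multistart grid; used internally by the
#'   bootstrap for speed.
#' @return A `psychometric_fit`: amplitude, `mu` and `sigma` (log10 units),
#'   `pse`, `weber_fraction`, `r_squared`, `converged`, and diagnostics. A
#'   degenerate fit (flat data, width at its bound, vanishing amplitude, or
#'   optimizer failure) is returned with `converged = FALSE` and a warning,
#'   never silently.
#' @examples
#' plan <- build_session_plan("duration_while", n_blocks = 1)
#' trials <- simulate_cohort(plan, cohort_params(n_participants = 5, seed = 1))
#' fit <- fit_gaussian(aggregate_proportions(trials, phase = "T1"))
#' fit$pse
#' @export
fit_gaussian <- function(props, weighted = FALSE, starts = NULL) {
  if (!all(c("level", "p_same") %in% names(props))) {
    abort_invalid("`props` needs columns `level` and `p_same`.")
  }
  if (!is.null(attr(props, "grouping")) &&
    attr(props, "grouping") == "per_participant") {
    abort_invalid(
      "`props` is per-participant; fit each participant separately (see fit_table())."
    )
  }
  keep <- is.finite(props$p_same)
  lev <- props$level[keep]
  y <- props$p_same[keep]
  if (length(unique(lev)) < 4) {
    rlang::abort(
      "At least 4 distinct levels with defined proportions are required.",
      class = c("samediff_insufficient_data", "samediff_error")
    )
  }
  x <- log10(lev)
  w <- if (weighted && "n_total" %in% names(props)) props$n_total[keep] else rep(1, length(y))

  degenerate_result <- function(reason) {
    warning(sprintf("Gaussian fit did not converge: %s", reason), call. = FALSE)
    structure(
      list(
        amplitude = NA_real_, mu = NA_real_, sigma = NA_real_,
        pse = NA_real_, weber_fraction = NA_real_, r_squared = NA_real_,
        converged = FALSE, n_levels = length(y), ss_res = NA_real_,
        diagnostics = reason
      ),
      class = "psychometric_fit"
    )
  }

  if (diff(range(y)) < 1e-9) {
    return(degenerate_result("constant proportions at all levels (sigma unbounded)"))
  }

  if (is.null(starts)) starts <- default_starts(x, y)
  core <- fit_gauss_core(x, y, w, starts)
  fit <- core$fit
  if (is.null(fit)) {
    return(degenerate_result("all optimizer starts failed"))
  }
  par <- unname(fit$par)
  at_sigma_bound <- par[3] >= core$upper[3] - 1e-6
  tiny_amplitude <- par[1] <= core$lower[1] + 1e-6
  if (fit$convergence != 0 || at_sigma_bound || tiny_amplitude) {
    return(degenerate_result(sprintf(
      "convergence code %d%s%s", fit$convergence,
      if (at_sigma_bound) "; width at upper bound" else "",
      if (tiny_amplitude) "; amplitude at lower bound" else ""
    )))
  }
  yhat <- par[1] * exp(-(x - par[2])^2 / (2 * par[3]^2))
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      amplitude = par[1], mu = par[2], sigma = par[3],
      pse = 10^par[2], weber_fraction = 10^par[3] - 1,
      r_squared = 1 - ss_res / ss_tot,
      converged = TRUE, n_levels = length(y), ss_res = ss_res,
      diagnostics = NULL
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<psychometric_fit> NOT CONVERGED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<psychometric_fit> PSE %.4g, Wf %.3f, A %.3f, sigma %.4f (log10), R^2 %.4f\n",
    x$pse, x$weber_fraction, x$amplitude, x$sigma, x$r_squared
  ))
  invisible(x)
}

#' Predicted "same" proportion from a fitted psychometric function
#'
#' @param object A `psychometric_fit`.
#' @param magnitudes Test magnitudes at which to evaluate the fit.
#' @param ... Unused.
#' @return Predicted proportions.
#' @export
predict.psychometric_fit <- function(object, magnitudes, ...) {
  if (!object$converged) abort_invalid("Cannot predict from a non-converged fit.")
  object$amplitude *
    exp(-(log10(magnitudes) - object$mu)^2 / (2 * object$sigma^2))
}

#' Perceptual bias as a signed percentage
#'
#' `Bias = (Reference - PSE) / Reference * 100`. Positive values mean the
#' PSE sits below the reference, i.e. the test magnitudes were overestimated
#' (a shorter test already matches the remembered reference).
#'
#' @param reference Reference magnitude (> 0).
#' @param pse Fitted point of subjective equality.
#' @return Signed percent bias.
#' @examples
#' bias_percent(600, 513) # ~14.5, the running-induced overestimation
#' @export
bias_percent <- function(reference, pse) {
  reference <- check_positive(reference, "reference")
  (reference - pse) / reference * 100
}

#' Weber fraction from a fitted log-Gaussian width
#'
#' The Weber fraction is the antilog of the fitted Gaussian's standard
#' deviation minus one: `base^sigma_log - 1`. It is invariant to the log
#' base used for fitting provided the width is exponentiated in the same
#' base.
#'
#' @param sigma_log Fitted width in `log_base` units (> 0).
#' @param log_base Base of the logarithm the width is expressed in.
#' @return Dimensionless Weber fraction.
#' @seealso [weber_fraction_jnd()] for the just-noticeable-difference form.
#' @export
weber_fraction <- function(sigma_log, log_base = 10) {
  if (!is.numeric(sigma_log) || any(sigma_log <= 0)) {
    abort_invalid("`sigma_log` must be positive.")
  }
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1) {
    abort_invalid("`log_base` must be > 1.")
  }
  log_base^sigma_log - 1
}

#' Weber fraction as JND / PSE
#'
#' Alternative definition: the just-noticeable difference, taken as the
#' half-width of the fitted Gaussian expressed in linear stimulus units,
#' divided by the PSE. For a Gaussian in log10 units this equals
#' `(10^sigma - 10^(-sigma)) / 2`, which converges to the antilog-minus-one
#' form of [weber_fraction()] as `sigma` shrinks and differs from it only at
#' second order in `sigma`.
#'
#' @param fit A converged `psychometric_fit`.
#' @return Dimensionless Weber fraction.
#' @export
weber_fraction_jnd <- function(fit) {
  if (!inherits(fit, "psychometric_fit") || !fit$converged) {
    abort_invalid("`fit` must be a converged psychometric_fit.")
  }
  jnd <- (10^(fit$mu + fit$sigma) - 10^(fit$mu - fit$sigma)) / 2
  jnd / fit$pse
}

#' Fit every participant/phase cell of a trial table
#'
#' Convenience wrapper producing one fit summary row per (participant or
#' aggregate) x phase combination, in the canonical export schema.
#'
#' @param trials Canonical trial table.
#' @param grouping `"aggregate"` or `"per_participant"`.
#' @param reference Reference magnitude for the bias column; inferred as the
#'   modal test magnitude when `NULL` (the reference is presented three
#'   times as often as any other level).
#' @param weighted Passed to [fit_gaussian()].
#' @return A tibble with columns `participant_id`, `experiment_kind`,
#'   `phase`, `A`, `mu`, `sigma`, `pse`, `weber_fraction`, `bias_percent`,
#'   `r_squared`, `converged`.
#' @export
fit_table <- function(trials, grouping = c("aggregate", "per_participant"),
                      reference = NULL, weighted = FALSE) {
  grouping <- match.arg(grouping)
  check_trial_table(trials)
  if (is.null(reference)) reference <- infer_reference(trials)
  kinds <- unique(trials$experiment_kind)
  cells <- unique(trials[, c(
    if (grouping == "per_participant") "participant_id" else NULL,
    "phase"
  ), drop = FALSE])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$phase == cells$phase[i], ]
    pid <- "AGGREGATE"
    if (grouping == "per_participant") {
      pid <- cells$participant_id[i]
      sub <- sub[sub$participant_id == pid, ]
    }
    fit <- suppressWarnings(fit_gaussian(
      aggregate_proportions(sub),
      weighted = weighted
    ))
    tibble::tibble(
      participant_id = pid,
      experiment_kind = paste(kinds, collapse = "+"),
      phase = cells$phase[i],
      A = fit$amplitude, mu = fit$mu, sigma = fit$sigma,
      pse = fit$pse, weber_fraction = fit$weber_fraction,
      bias_percent = bias_percent(reference, fit$pse),
      r_squared = fit$r_squared, converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

# the reference level is the one presented most often
#' @noRd
infer_reference <- function(trials) {
  tab <- table(trials$test_magnitude)
  as.numeric(names(tab)[which.max(tab)])
}
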