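#' Generative observer parameters for the same/different judgment
#'
#' The synthetic observer perceives a test magnitude `x` against a memorized
#' reference through a multiplicative perceptual gain `g` (phase-specific:
#' `g > 1` means tests are perceived larger, so the point of subjective
#' equality falls at `reference / g`, below the reference). The internal
#' difference signal is `ln(g * x / reference)` corrupted by zero-mean
#' Gaussian noise with standard deviation `sqrt(sensory_noise^2 +
#' memory_noise^2)` (natural-log units); the observer answers "same" when
#' the noisy signal falls within `criterion` of zero. With probability
#' `lapse_rate` the observer lapses and answers "same" with probability
#' `lapse_same_prob`, which keeps the peak of the psychometric curve below 1.
#'
#' @param gain_by_phase Named numeric vector mapping phase labels to
#'   perceptual gains; phases not named default to gain 1.
#' @param sensory_noise,memory_noise Noise standard deviations in natural-log
#'   units (>= 0, not both 0).
#' @param criterion Half-width of the "same" region in natural-log units (> 0).
#' @param lapse_rate Lapse probability in [0, 1]; at 1 the curve is flat at
#'   `lapse_same_prob` (pure guessing).
#' @param lapse_same_prob Probability of answering "same" on a lapse.
#' @return An `observer_params` object.
#' @export
observer_params <- function(gain_by_phase = c(RUN_TEST = 600 / 513),
                            sensory_noise = 0.11, memory_noise = 0.10,
                            criterion = 0.25, lapse_rate = 0.12,
                            lapse_same_prob = 0.5) {
  if (length(gain_by_phase) > 0 &&
    (is.null(names(gain_by_phase)) || any(names(gain_by_phase) == ""))) {
    abort_invalid("`gain_by_phase` must be a named numeric vector.")
  }
  if (any(gain_by_phase <= 0)) abort_invalid("Gains must be positive.")
  if (sensory_noise < 0 || memory_noise < 0) {
    abort_invalid("Noise standard deviations must be >= 0.")
  }
  criterion <- check_positive(criterion, "criterion")
  if (lapse_rate < 0 || lapse_rate > 1) abort_invalid("`lapse_rate` must be in [0, 1].")
  if (lapse_same_prob < 0 || lapse_same_prob > 1) {
    abort_invalid("`lapse_same_prob` must be in [0, 1].")
  }
  structure(
    list(
      gain_by_phase = gain_by_phase, sensory_noise = sensory_noise,
      memory_noise = memory_noise, criterion = criterion,
      lapse_rate = lapse_rate, lapse_same_prob = lapse_same_prob
    ),
    class = "observer_params"
  )
}

#' Default observer parameters per experiment kind
#'
#' Duration judgments are noisier than numerosity judgments: the duration
#' defaults yield a fitted Weber fraction near 0.23 and the numerosity
#' defaults near 0.14. The while-running phases carry a gain of 600/513
#' for duration (the running-induced dilation, placing the expected
#' aggregate PSE at 513 ms against the 600 ms reference) and 1 for
#' numerosity (unaffected by running); all baseline phases have gain 1.
#'
#' @param kind Experiment kind (see [build_session_plan()]).
#' @return An [observer_params()] object.
#' @export
default_observer_params <- function(kind = c(
                                      "duration_while", "duration_after",
                                      "numerosity_while"
                                    )) {
  kind <- match.arg(kind)
  switch(kind,
    duration_while = observer_params(gain_by_phase = c(RUN_TEST = 600 / 513)),
    duration_after = observer_params(gain_by_phase = c(TEST_AFTER = 1)),
    numerosity_while = observer_params(
      gain_by_phase = c(RUN_TEST = 1),
      sensory_noise = 0.07, memory_noise = 0.06, criterion = 0.17
    )
  )
}

#' @noRd
phase_gain <- function(params, phase) {
  g <- unname(params$gain_by_phase[phase])
  ifelse(is.na(g), 1, g)
}

#' Closed-form probability of a "same" response
#'
#' Under the gain + criterion observer the probability of answering "same"
#' to a test magnitude `x` is
#' `(1 - lambda) * (Phi((c - mu)/s) - Phi((-c - mu)/s)) + lambda * gamma`,
#' with `mu = ln(g * x / reference)`, `s = sqrt(sensory_noise^2 +
#' memory_noise^2)`, `c` the criterion, `lambda` the lapse rate and `gamma`
#' the lapse guess-same probability. The curve is symmetric in `ln(x)`
#' around its maximum at exactly `x = reference / g`.
#'
#' @param test Test magnitude(s), positive; vectorized.
#' @param reference Reference magnitude, positive.
#' @param params An [observer_params()] object.
#' @param phase Phase label used to look up the gain (unknown labels mean
#'   gain 1).
#' @return Probability of "same" for each test magnitude.
#' @examples
#' p <- analytic_p_same(duration_stimuli()$tests, 600, observer_params())
#' @export
analytic_p_same <- function(test, reference, params, phase = "T1") {
  if (!inherits(params, "observer_params")) {
    abort_invalid("`params` must be an observer_params object.")
  }
  if (any(test <= 0) || reference <= 0) {
    abort_invalid("Magnitudes must be positive.")
  }
  s <- sqrt(params$sensory_noise^2 + params$memory_noise^2)
  if (s == 0) {
    rlang::abort(
      "Deterministic observer (zero combined noise) is not supported.",
      class = c("samediff_degenerate_model", "samediff_error")
    )
  }
  g <- phase_gain(params, phase)
  mu <- log(g * test / reference)
  cc <- params$criterion
  lam <- params$lapse_rate
  (1 - lam) * (pnorm((cc - mu) / s) - pnorm((-cc - mu) / s)) +
    lam * params$lapse_same_prob
}

#' Simulate the trials of one decoding phase
#'
#' Draws one Bernoulli "same"/"different" response per scheduled trial with
#' probability [analytic_p_same()]. Trial times are spaced evenly through a
#' nominal 5-minute decoding phase (300/66 s per trial by default).
#'
#' @param schedule A [build_decoding_schedule()] result.
#' @param reference Reference magnitude.
#' @param params An [observer_params()] object.
#' @param phase Phase label (selects the gain and is recorded per trial).
#' @param seed Integer seed; identical seeds give identical responses.
#' @param trial_duration_s Nominal seconds per trial.
#' @return A tibble with `phase`, `trial_index`, `test_magnitude`,
#'   `response`, `seconds_since_phase_start`.
#' @export
simulate_trials <- function(schedule, reference, params, phase = "T1",
                            seed = 1, trial_duration_s = 300 / 66) {
  if (!inherits(schedule, "decoding_schedule")) {
    abort_invalid("`schedule` must be a decoding_schedule.")
  }
  p <- analytic_p_same(schedule$trials, reference, params, phase)
  same <- withr::with_seed(as.integer(seed), runif(length(p)) < p)
  tibble::new_tibble(
    list(
      phase = rep(phase, length(p)),
      trial_index = seq_along(p),
      test_magnitude = schedule$trials,
      response = ifelse(same, "same", "different"),
      seconds_since_phase_start = seq_along(p) * trial_duration_s
    ),
    nrow = length(p)
  )
}

#' Cohort-level variability parameters
#'
#' Between-participant variability enters as log-normal perturbations of the
#' perceptual gain and the criterion: participant `i` multiplies every
#' phase gain by `exp(e_i)` and the criterion by `exp(f_i)`, with
#' `e_i, f_i ~ N(0, between_subject_sd^2)`.
#'
#' @param n_participants Cohort size (canonically 15).
#' @param between_subject_sd Standard deviation of the log-gain and
#'   log-criterion perturbations (>= 0).
#' @param seed Root seed for all cohort randomness.
#' @return A `cohort_params` object.
#' @export
cohort_params <- function(n_participants = 15, between_subject_sd = 0.06,
                          seed = 1) {
  n_participants <- check_count(n_participants, "n_participants")
  if (between_subject_sd < 0) abort_invalid("`between_subject_sd` must be >= 0.")
  structure(
    list(
      n_participants = n_participants,
      between_subject_sd = between_subject_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

#' Simulate a full cohort through a session plan
#'
#' Draws per-participant gain and criterion perturbations (see
#' [cohort_params()]), then simulates every decoding phase of every block
#' for every participant with its own freshly shuffled schedule. All
#' randomness derives from the cohort seed, split hierarchically, so the
#' same seed reproduces the table exactly.
#'
#' @param plan A [build_session_plan()] result.
#' @param cohort A [cohort_params()] object.
#' @param base_params Observer parameters shared by the cohort; defaults to
#'   [default_observer_params()] for the plan's kind.
#' @return The canonical trial table: a tibble with columns
#'   `participant_id`, `experiment_kind`, `block`, `phase`, `trial_index`,
#'   `test_magnitude`, `response`, `seconds_since_phase_start`.
#' @examples
#' plan <- build_session_plan("duration_while")
#' trials <- simulate_cohort(plan, cohort_params(n_participants = 2, seed = 7))
#' @export
simulate_cohort <- function(plan, cohort = cohort_params(),
                            base_params = default_observer_params(plan$experiment_kind)) {
  if (!inherits(plan, "session_plan")) abort_invalid("`plan` must be a session_plan.")
  if (!inherits(cohort, "cohort_params")) abort_invalid("`cohort` must be cohort_params.")
  n <- cohort$n_participants
  decoding <- plan$phases[plan$phases$phase_kind == "decoding", ]
  n_phase <- nrow(decoding)

  perturb <- withr::with_seed(
    cohort$seed,
    matrix(rnorm(2L * n, 0, cohort$between_subject_sd), nrow = n)
  )
  seeds <- matrix(
    derive_seeds(cohort$seed + 1L, n * n_phase * 2L),
    nrow = n
  )

  out <- vector("list", n)
  for (i in seq_len(n)) {
    params_i <- base_params
    params_i$gain_by_phase <- base_params$gain_by_phase * exp(perturb[i, 1])
    params_i$criterion <- base_params$criterion * exp(perturb[i, 2])
    rows <- vector("list", n_phase)
    for (j in seq_len(n_phase)) {
      sched <- build_decoding_schedule(
        plan$stimuli, plan$reps_nonreference, plan$reps_reference,
        seed = seeds[i, 2L * j - 1L]
      )
      tr <- simulate_trials(
        sched, plan$stimuli$reference, params_i,
        phase = decoding$phase_label[j], seed = seeds[i, 2L * j]
      )
      tr$block <- decoding$block[j]
      rows[[j]] <- tr
    }
    pdat <- dplyr::bind_rows(rows)
    pdat$participant_id <- sprintf("P%02d", i)
    pdat$experiment_kind <- plan$experiment_kind
    out[[i]] <- pdat
  }
  dplyr::bind_rows(out)[, trial_table_columns()]
}
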