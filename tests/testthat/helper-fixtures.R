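# Shared fixtures, built once per test run. All randomness is seeded.

fix_plan <- build_session_plan("duration_while")

# a 15-participant while-running cohort at the canonical trial counts
fix_trials <- simulate_cohort(fix_plan, cohort_params(n_participants = 15, seed = 42))

# a single-level "schedule" for Monte-Carlo checks against the closed form
constant_schedule <- function(magnitude, n) {
  structure(
    list(
      trials = rep(magnitude, n), reps_nonreference = 1L,
      reps_reference = n, shuffle_seed = 0L, reference = magnitude
    ),
    class = "decoding_schedule"
  )
}

# hand-built trial table: one participant, one phase, arbitrary counts
make_trials <- function(levels, n_same, n_total, phase = "T1",
                        participant = "P01", kind = "duration_while") {
  rows <- lapply(seq_along(levels), function(i) {
    tibble::tibble(
      participant_id = participant, experiment_kind = kind, block = 1L,
      phase = phase, trial_index = NA_integer_,
      test_magnitude = levels[i],
      response = rep(c("same", "different"), c(n_same[i], n_total[i] - n_same[i])),
      seconds_since_phase_start = NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  out$trial_index <- seq_len(nrow(out))
  out$seconds_since_phase_start <- out$trial_index * 4.5
  out
}
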