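#' Construct a stimulus set for a same/different comparison task
#'
#' A stimulus set is a reference magnitude together with an odd-length,
#' ascending list of test magnitudes whose middle element is the reference.
#' Sets are usually built with [make_log_spaced_tests()]; this constructor
#' exists for explicit lists, e.g. the printed dot-numerosity levels, which
#' depart from a single-ratio log spacing at one level (17 where the
#' outward-generation rule gives 16).
#'
#' @param reference Reference magnitude (e.g. 600 ms, or 24 dots).
#' @param tests Ascending vector of test magnitudes; odd length, middle
#'   element equal to `reference`, which must appear exactly once.
#' @param unit_label Unit string carried for display ("ms", "dots", ...).
#' @param rounded Whether `tests` are integer-rounded display values.
#' @param tests_exact Unrounded magnitudes retained for fitting; defaults to
#'   `tests`.
#' @return A `stimulus_set` object.
#' @seealso [make_log_spaced_tests()], [duration_stimuli()],
#'   [numerosity_stimuli()]
#' @export
stimulus_set <- function(reference, tests, unit_label = "",
                         rounded = FALSE, tests_exact = tests) {
  reference <- check_positive(reference, "reference")
  if (!is.numeric(tests) || length(tests) < 3 || length(tests) %% 2 == 0) {
    abort_invalid("`tests` must be a numeric vector of odd length >= 3.")
  }
  if (any(tests <= 0)) abort_invalid("All test magnitudes must be positive.")
  if (is.unsorted(tests, strictly = TRUE)) {
    abort_invalid("`tests` must be strictly ascending.")
  }
  mid <- (length(tests) + 1L) / 2L
  if (tests[mid] != reference) {
    abort_invalid("The middle test magnitude must equal the reference.")
  }
  if (sum(tests == reference) != 1L) {
    abort_invalid("Exactly one test magnitude may equal the reference.")
  }
  structure(
    list(
      reference = reference, tests = as.numeric(tests),
      unit_label = unit_label, rounded = isTRUE(rounded),
      tests_exact = as.numeric(tests_exact)
    ),
    class = "stimulus_set"
  )
}

#' Generate log-spaced test magnitudes around a reference
#'
#' Levels are generated outward from the reference anchor as
#' `reference * r^k` for `k = -steps_per_side, ..., steps_per_side`, with the
#' common ratio `r = (extreme / reference)^(1 / steps_per_side)`. Outward
#' generation (rather than end-to-end interpolation) is what reproduces the
#' canonical 9-level duration list 284, 342, 413, 498, 600, 723, 872, 1052,
#' 1268 ms after integer rounding; interpolation rounds one level to 724.
#' Rounding is half-away-from-zero; the unrounded magnitudes are retained in
#' the returned set for fitting.
#'
#' @param reference Reference magnitude (middle level), > 0.
#' @param extreme Largest test magnitude, > `reference`.
#' @param steps_per_side Number of levels on each side of the reference.
#' @param round_to_integer Round the display levels to nearest integers.
#' @param unit_label Unit string ("ms", "dots", ...).
#' @return A [stimulus_set()] with `2 * steps_per_side + 1` levels.
#' @examples
#' make_log_spaced_tests(600, 1268, 4, round_to_integer = TRUE)
#' @export
make_log_spaced_tests <- function(reference, extreme, steps_per_side = 4,
                                  round_to_integer = FALSE, unit_label = "") {
  reference <- check_positive(reference, "reference")
  extreme <- check_positive(extreme, "extreme")
  steps_per_side <- check_count(steps_per_side, "steps_per_side")
  if (extreme <= reference) {
    abort_invalid("`extreme` must be strictly greater than `reference`.")
  }
  r <- (extreme / reference)^(1 / steps_per_side)
  k <- seq.int(-steps_per_side, steps_per_side)
  exact <- reference * r^k
  exact[steps_per_side + 1L] <- reference # anchor the middle element exactly
  tests <- if (round_to_integer) round_half_away(exact) else exact
  stimulus_set(reference, tests,
    unit_label = unit_label,
    rounded = round_to_integer, tests_exact = exact
  )
}

#' Canonical duration stimulus set (600 ms reference)
#'
#' Nine log-spaced durations around a 600 ms reference, integer-rounded:
#' 284, 342, 413, 498, 600, 723, 872, 1052, 1268 ms.
#' @return A [stimulus_set()].
#' @export
duration_stimuli <- function() {
  make_log_spaced_tests(600, 1268, 4, round_to_integer = TRUE, unit_label = "ms")
}

#' Canonical numerosity stimulus set (24-dot reference)
#'
#' The nine printed dot numerosities 11, 14, 17, 20, 24, 29, 35, 42, 51,
#' stored as an explicit list: no single-ratio log-spacing rule reproduces
#' the printed 17 (outward generation from 24 with extreme 51 rounds to 16),
#' so the published levels are taken verbatim.
#' @return A [stimulus_set()].
#' @export
numerosity_stimuli <- function() {
  stimulus_set(24, c(11, 14, 17, 20, 24, 29, 35, 42, 51),
    unit_label = "dots", rounded = TRUE
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf(
    "<stimulus_set> reference %g %s; %d levels: %s\n",
    x$reference, x$unit_label, length(x$tests),
    paste(x$tests, collapse = ", ")
  ))
  invisible(x)
}

#' Build a shuffled decoding-phase trial schedule
#'
#' A decoding phase presents every non-reference test level
#' `reps_nonreference` times and the reference `reps_reference` times, in a
#' uniformly shuffled order. With the canonical counts (6 and 18) a 9-level
#' set yields the 66-trial decoding phase (8 x 6 + 18). The same seed always
#' reproduces the same order.
#'
#' @param stimuli A [stimulus_set()].
#' @param reps_nonreference Presentations per non-reference level.
#' @param reps_reference Presentations of the reference level.
#' @param seed Integer shuffle seed.
#' @return A `decoding_schedule`: list with `trials` (ordered magnitudes),
#'   the repetition counts and the seed.
#' @export
build_decoding_schedule <- function(stimuli, reps_nonreference = 6,
                                    reps_reference = 18, seed = 1) {
  if (!inherits(stimuli, "stimulus_set")) {
    abort_invalid("`stimuli` must be a stimulus_set.")
  }
  reps_nonreference <- check_count(reps_nonreference, "reps_nonreference")
  reps_reference <- check_count(reps_reference, "reps_reference")
  nonref <- stimuli$tests[stimuli$tests != stimuli$reference]
  pool <- c(
    rep(nonref, each = reps_nonreference),
    rep(stimuli$reference, reps_reference)
  )
  trials <- withr::with_seed(as.integer(seed), sample(pool))
  structure(
    list(
      trials = trials,
      reps_nonreference = reps_nonreference,
      reps_reference = reps_reference,
      shuffle_seed = as.integer(seed),
      reference = stimuli$reference
    ),
    class = "decoding_schedule"
  )
}

#' @export
print.decoding_schedule <- function(x, ...) {
  cat(sprintf(
    "<decoding_schedule> %d trials (%d per non-reference level, %d reference), seed %d\n",
    length(x$trials), x$reps_nonreference, x$reps_reference, x$shuffle_seed
  ))
  invisible(x)
}

# phase layouts: the while-running block runs
# training -> encoding -> rest(3 min) -> T1 -> encoding -> warm-up(3 min) ->
# decoding while running -> rest -> encoding -> T2; the after-running block
# has an 8-min pre-baseline rest, an 8-min run (3 warm-up + 5 plateau, no
# stimuli) and the test immediately after the treadmill stops, with no T2.
session_phase_layout <- function(kind, n_decoding) {
  decoding <- function(label) {
    list(label = label, kind = "decoding", duration_s = NA_real_, n_trials = n_decoding)
  }
  enc <- list(label = "encoding", kind = "encoding", duration_s = NA_real_, n_trials = 5)
  switch(kind,
    duration_while = ,
    numerosity_while = list(
      list(label = "training", kind = "training", duration_s = NA_real_, n_trials = 9),
      enc,
      list(label = "rest", kind = "rest", duration_s = 180, n_trials = 0),
      decoding("T1"),
      enc,
      list(label = "RUN_WARMUP", kind = "run", duration_s = 180, n_trials = 0),
      decoding("RUN_TEST"),
      list(label = "rest", kind = "rest", duration_s = 600, n_trials = 0),
      enc,
      decoding("T2")
    ),
    duration_after = list(
      list(label = "training", kind = "training", duration_s = NA_real_, n_trials = 9),
      enc,
      list(label = "rest", kind = "rest", duration_s = 480, n_trials = 0),
      decoding("T1"),
      enc,
      list(label = "RUN_WARMUP", kind = "run", duration_s = 180, n_trials = 0),
      list(label = "RUN_PLATEAU", kind = "run", duration_s = 300, n_trials = 0),
      decoding("TEST_AFTER"),
      list(label = "rest", kind = "rest", duration_s = 600, n_trials = 0)
    ),
    abort_invalid(sprintf("Unknown experiment kind '%s'.", kind))
  )
}

#' Build a full session plan
#'
#' Lays out the ordered phases of a session for one of the three experiment
#' kinds (`duration_while`, `duration_after`, `numerosity_while`) across
#' `n_blocks` block repetitions. The while-running kinds measure three
#' decoding phases per block (T1, RUN_TEST, T2); the after-running kind
#' measures two (T1, TEST_AFTER), with the test starting immediately after
#' the treadmill stops. Training (a fixed nine-trial placeholder for the
#' to-criterion feedback procedure) occurs only in the first block.
#'
#' @param kind One of `"duration_while"`, `"duration_after"`,
#'   `"numerosity_while"`.
#' @param stimuli A [stimulus_set()]; defaults to the canonical set for the
#'   kind.
#' @param n_blocks Number of block repetitions (canonically 2).
#' @param reps_nonreference,reps_reference Decoding-phase repetition counts
#'   (canonically 6 and 18, i.e. 66 trials per decoding phase).
#' @return A `session_plan`: the phase table (one row per phase with block,
#'   label, kind, nominal duration and trial count), the measurement-phase
#'   labels, and the total decoding-trial count
#'   (`n_measurement_phases * n_blocks * trials_per_phase`).
#' @examples
#' plan <- build_session_plan("duration_while")
#' plan$n_decoding_trials # 396
#' @export
build_session_plan <- function(kind, stimuli = NULL, n_blocks = 2,
                               reps_nonreference = 6, reps_reference = 18) {
  if (!is.character(kind) || length(kind) != 1L ||
    !kind %in% c("duration_while", "duration_after", "numerosity_while")) {
    abort_invalid(
      "`kind` must be one of 'duration_while', 'duration_after', 'numerosity_while'."
    )
  }
  if (is.null(stimuli)) {
    stimuli <- if (kind == "numerosity_while") numerosity_stimuli() else duration_stimuli()
  }
  if (!inherits(stimuli, "stimulus_set")) {
    abort_invalid("`stimuli` must be a stimulus_set.")
  }
  n_blocks <- check_count(n_blocks, "n_blocks")
  reps_nonreference <- check_count(reps_nonreference, "reps_nonreference")
  reps_reference <- check_count(reps_reference, "reps_reference")
  n_decoding <- (length(stimuli$tests) - 1L) * reps_nonreference + reps_reference

  rows <- list()
  for (b in seq_len(n_blocks)) {
    layout <- session_phase_layout(kind, n_decoding)
    if (b > 1L) layout <- Filter(function(p) p$label != "training", layout)
    for (i in seq_along(layout)) {
      p <- layout[[i]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = b, phase_index = i, phase_label = p$label,
        phase_kind = p$kind, duration_s = p$duration_s, n_trials = p$n_trials
      )
    }
  }
  phases <- dplyr::bind_rows(rows)
  measurement <- unique(phases$phase_label[phases$phase_kind == "decoding"])
  structure(
    list(
      experiment_kind = kind, stimuli = stimuli, n_blocks = n_blocks,
      reps_nonreference = reps_nonreference, reps_reference = reps_reference,
      phases = phases, measurement_phases = measurement,
      trials_per_decoding = n_decoding,
      n_decoding_trials = sum(phases$n_trials[phases$phase_kind == "decoding"])
    ),
    class = "session_plan"
  )
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(
    "<session_plan> %s: %d block(s), measurement phases %s, %d decoding trials total\n",
    x$experiment_kind, x$n_blocks,
    paste(x$measurement_phases, collapse = "/"), x$n_decoding_trials
  ))
  invisible(x)
}

#' Age-predicted target heart rate
#'
#' Maximum heart rate is predicted from chronological age as
#' `208 - 0.7 * age` (beats per minute); the exercise target is a fraction
#' of that maximum (0.8 in the running protocol).
#'
#' @param age Age in years (0 < age < 120).
#' @param fraction Fraction of the age-predicted maximum (0 < fraction <= 1).
#' @return Target heart rate in bpm.
#' @examples
#' target_heart_rate(27.3, 0.8)
#' @export
target_heart_rate <- function(age, fraction = 0.8) {
  if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
    age <= 0 || age >= 120) {
    abort_invalid("`age` must be a single number in (0, 120).")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
    fraction <= 0 || fraction > 1) {
    abort_invalid("`fraction` must be in (0, 1].")
  }
  fraction * (208 - 0.7 * age)
}

#' Tabulate the decoding schedules of a session plan
#'
#' Expands a [build_session_plan()] into one row per decoding trial with a
#' freshly shuffled schedule per decoding phase, deterministically derived
#' from `seed`.
#'
#' @param plan A `session_plan`.
#' @param seed Integer root seed for the per-phase shuffles.
#' @return A tibble with columns `block`, `phase`, `trial_index`,
#'   `test_magnitude`.
#' @export
schedule_table <- function(plan, seed = 1) {
  if (!inherits(plan, "session_plan")) abort_invalid("`plan` must be a session_plan.")
  decoding <- plan$phases[plan$phases$phase_kind == "decoding", ]
  seeds <- derive_seeds(seed, nrow(decoding))
  rows <- lapply(seq_len(nrow(decoding)), function(i) {
    sched <- build_decoding_schedule(
      plan$stimuli, plan$reps_nonreference, plan$reps_reference,
      seed = seeds[i]
    )
    tibble::tibble(
      block = decoding$block[i],
      phase = decoding$phase_label[i],
      trial_index = seq_along(sched$trials),
      test_magnitude = sched$trials
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize / restore a session configuration
#'
#' Writes the parameters needed to rebuild a session plan (experiment kind,
#' reference, test levels, repetition counts, block count, seed) as a
#' structured text (YAML) file with a versioned schema key, and reads it
#' back.
#'
#' @param plan A `session_plan`.
#' @param path File path.
#' @param seed Shuffle seed recorded alongside the design.
#' @return `write_session_config()` returns `path` invisibly;
#'   `read_session_config()` returns a `session_plan` (with the recorded
#'   seed attached as attribute `"seed"`).
#' @export
write_session_config <- function(plan, path, seed = 1) {
  if (!inherits(plan, "session_plan")) abort_invalid("`plan` must be a session_plan.")
  cfg <- list(
    schema_version = 1L,
    experiment_kind = plan$experiment_kind,
    reference = plan$stimuli$reference,
    tests = plan$stimuli$tests,
    unit_label = plan$stimuli$unit_label,
    reps_nonreference = plan$reps_nonreference,
    reps_reference = plan$reps_reference,
    n_blocks = plan$n_blocks,
    seed = as.integer(seed)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stimuli <- stimulus_set(cfg$reference, as.numeric(cfg$tests),
    unit_label = cfg$unit_label %||% "", rounded = TRUE
  )
  plan <- build_session_plan(
    cfg$experiment_kind, stimuli,
    n_blocks = cfg$n_blocks,
    reps_nonreference = cfg$reps_nonreference,
    reps_reference = cfg$reps_reference
  )
  attr(plan, "seed") <- cfg$seed
  plan
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
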