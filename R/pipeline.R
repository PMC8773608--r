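#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run — design, observer, cohort,
#' inference — into one list that serializes to a versioned YAML config.
#' The root seed recorded here feeds every stochastic stage.
#'
#' @param experiment_kind See [build_session_plan()].
#' @param reference,extreme,steps_per_side,round_levels,unit_label Stimulus
#'   design; ignored (the explicit printed list is used) when
#'   `levels` is given or the kind is `numerosity_while`.
#' @param levels Optional explicit test-level vector.
#' @param n_blocks,reps_nonreference,reps_reference Session design.
#' @param n_participants,between_subject_sd Cohort structure.
#' @param observer Optional [observer_params()]; defaults per kind.
#' @param n_bootstrap Bootstrap iterations for comparisons.
#' @param alpha,bonferroni_k Significance threshold and family size.
#' @param root_seed Root seed for all randomness.
#' @param output_directory Where `cmd_*` drivers write files.
#' @return A `run_config` list.
#' @export
run_config <- function(experiment_kind = "duration_while",
                       reference = NULL, extreme = NULL, steps_per_side = 4,
                       round_levels = TRUE, unit_label = NULL, levels = NULL,
                       n_blocks = 2, reps_nonreference = 6, reps_reference = 18,
                       n_participants = 15, between_subject_sd = 0.06,
                       observer = NULL, n_bootstrap = 10000,
                       alpha = 0.05, bonferroni_k = 3,
                       root_seed = 1, output_directory = ".") {
  numerosity <- experiment_kind == "numerosity_while"
  cfg <- list(
    schema_version = 1L,
    experiment_kind = experiment_kind,
    reference = reference %||% if (numerosity) 24 else 600,
    extreme = extreme %||% if (numerosity) 51 else 1268,
    steps_per_side = steps_per_side,
    round_levels = round_levels,
    unit_label = unit_label %||% if (numerosity) "dots" else "ms",
    levels = levels,
    n_blocks = n_blocks,
    reps_nonreference = reps_nonreference,
    reps_reference = reps_reference,
    n_participants = n_participants,
    between_subject_sd = between_subject_sd,
    observer = observer,
    n_bootstrap = n_bootstrap,
    alpha = alpha,
    bonferroni_k = bonferroni_k,
    root_seed = as.integer(root_seed),
    output_directory = output_directory
  )
  structure(cfg, class = "run_config")
}

#' @noRd
config_stimuli <- function(config) {
  if (!is.null(config$levels)) {
    return(stimulus_set(config$reference, as.numeric(config$levels),
      unit_label = config$unit_label, rounded = TRUE
    ))
  }
  if (config$experiment_kind == "numerosity_while") {
    return(numerosity_stimuli())
  }
  make_log_spaced_tests(config$reference, config$extreme, config$steps_per_side,
    round_to_integer = config$round_levels, unit_label = config$unit_label
  )
}

#' @noRd
config_plan <- function(config) {
  build_session_plan(config$experiment_kind, config_stimuli(config),
    n_blocks = config$n_blocks,
    reps_nonreference = config$reps_nonreference,
    reps_reference = config$reps_reference
  )
}

#' @noRd
config_observer <- function(config) {
  config$observer %||% default_observer_params(config$experiment_kind)
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$observer)) x$observer <- unclass(x$observer)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  obs <- x$observer
  if (!is.null(obs)) {
    obs <- observer_params(
      gain_by_phase = unlist(obs$gain_by_phase),
      sensory_noise = obs$sensory_noise, memory_noise = obs$memory_noise,
      criterion = obs$criterion, lapse_rate = obs$lapse_rate,
      lapse_same_prob = obs$lapse_same_prob
    )
  }
  do.call(run_config, c(
    x[setdiff(names(x), c("schema_version", "observer"))],
    list(observer = obs)
  ))
}

#' @noRd
config_hash <- function(config) {
  text_hash(yaml::as.yaml(unclass(config)))
}

#' Read and write the canonical trial table
#'
#' Comma-separated files with the canonical column set (`participant_id`,
#' `experiment_kind`, `block`, `phase`, `trial_index`, `test_magnitude`,
#' `response`, `seconds_since_phase_start`). Reading validates the schema
#' and names any offending columns.
#'
#' @param trials Canonical trial table.
#' @param path File path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` the validated tibble.
#' @export
write_trial_table <- function(trials, path) {
  check_trial_table(trials)
  write.csv(trials[, trial_table_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  trials <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  check_trial_table(trials)
  trials
}

#' Simulate a cohort and write the canonical trial table
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `output_directory`.
#' @param write_heart Also write per-participant heart-rate traces
#'   (`heart_traces.csv`: `participant_id`, `t_s`, `hr_bpm`).
#' @return Invisibly, a list with the simulated `trials` tibble and the
#'   written `paths`.
#' @export
cmd_simulate <- function(config, out_dir = config$output_directory,
                         write_heart = FALSE) {
  plan <- config_plan(config)
  cohort <- cohort_params(
    config$n_participants, config$between_subject_sd,
    seed = config$root_seed
  )
  trials <- simulate_cohort(plan, cohort, config_observer(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  trial_path <- file.path(out_dir, "trials.csv")
  write_trial_table(trials, trial_path)
  log_info(
    "simulate: %d trials, %d participants, kind %s, seed %d -> %s",
    nrow(trials), config$n_participants, config$experiment_kind,
    config$root_seed, trial_path
  )
  paths <- trial_path
  if (write_heart) {
    hseeds <- derive_seeds(config$root_seed + 2L, config$n_participants)
    hr <- dplyr::bind_rows(lapply(seq_len(config$n_participants), function(i) {
      tr <- simulate_heart_trace(heart_trace_params(), seed = hseeds[i])
      tr$participant_id <- sprintf("P%02d", i)
      tr[, c("participant_id", "t_s", "hr_bpm")]
    }))
    hr_path <- file.path(out_dir, "heart_traces.csv")
    write.csv(hr, hr_path, row.names = FALSE)
    log_info("simulate: wrote heart traces -> %s", hr_path)
    paths <- c(paths, hr_path)
  }
  invisible(list(trials = trials, paths = paths))
}

#' Fit psychometric functions for every phase of a trial table
#'
#' @param trials Canonical trial table, or a path to one.
#' @param grouping `"aggregate"` or `"per_participant"`.
#' @param reference Reference magnitude (inferred from trial counts when
#'   `NULL`).
#' @param out_path Optional CSV path for the fit summary.
#' @return The fit summary tibble (see [fit_table()]).
#' @export
cmd_fit <- function(trials, grouping = "aggregate", reference = NULL,
                    out_path = NULL) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  fits <- fit_table(trials, grouping = grouping, reference = reference)
  if (any(!fits$converged)) {
    log_info("fit: %d of %d fits did not converge", sum(!fits$converged), nrow(fits))
  }
  if (!is.null(out_path)) {
    write.csv(fits, out_path, row.names = FALSE)
    log_info("fit: %d rows -> %s", nrow(fits), out_path)
  }
  fits
}

#' Bootstrap comparison report across phase contrasts
#'
#' Runs the full inference battery on a trial table: one bootstrap peak
#' distribution per phase, a Z-test per requested contrast with a
#' Bonferroni-corrected threshold, and (when several participants are
#' present) the per-participant paired t-test with Cohen's d and the JZS
#' Bayes factor for each contrast. The provenance block carries the seed,
#' iteration count and a config hash so an identical call regenerates the
#' report bit-for-bit.
#'
#' @param trials Canonical trial table, or a path to one.
#' @param contrasts List of length-2 character vectors of phase labels,
#'   `c(condition, baseline)`; defaults to the three duration contrasts
#'   (RUN vs T1, RUN vs T2, T1 vs T2) when those phases exist, otherwise
#'   all pairs of observed phases.
#' @param n_bootstrap Bootstrap iterations per phase.
#' @param alpha Family-wise level; corrected over `length(contrasts)`.
#' @param seed Root seed.
#' @param reference Reference magnitude (inferred when `NULL`).
#' @param config Optional [run_config()] recorded in the provenance block.
#' @return A `report_bundle`: `fits`, `bootstrap` (per-phase summaries),
#'   `comparisons` (tibble of Z and t rows), `provenance`.
#' @export
cmd_compare <- function(trials, contrasts = NULL, n_bootstrap = 1000,
                        alpha = 0.05, seed = 1, reference = NULL,
                        config = NULL) {
  if (is.character(trials)) trials <- read_trial_table(trials)
  check_trial_table(trials)
  phases <- unique(trials$phase)
  if (is.null(contrasts)) {
    contrasts <- if (all(c("RUN_TEST", "T1", "T2") %in% phases)) {
      list(c("RUN_TEST", "T1"), c("RUN_TEST", "T2"), c("T1", "T2"))
    } else {
      utils::combn(phases, 2, simplify = FALSE)
    }
  }
  bad <- setdiff(unique(unlist(contrasts)), phases)
  if (length(bad) > 0) {
    abort_invalid(paste0(
      "Unknown contrast phase(s): ", paste(bad, collapse = ", ")
    ))
  }
  if (is.null(reference)) reference <- infer_reference(trials)
  k <- length(contrasts)

  used <- unique(unlist(contrasts))
  seeds <- derive_seeds(seed, length(used))
  boots <- list()
  for (i in seq_along(used)) {
    boots[[used[i]]] <- bootstrap_pse(trials,
      phase = used[i],
      n_iterations = n_bootstrap, seed = seeds[i]
    )
  }

  n_participants <- length(unique(trials$participant_id))
  pfits <- if (n_participants >= 3) {
    fit_table(trials, grouping = "per_participant", reference = reference)
  } else {
    NULL
  }

  rows <- list()
  for (ct in contrasts) {
    zc <- z_compare(boots[[ct[1]]], boots[[ct[2]]],
      alpha = alpha, comparisons = k
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      contrast = paste(ct[1], "vs", ct[2]), statistic_kind = "bootstrap_z",
      statistic = zc$statistic, df = NA_real_, p_value = zc$p_value,
      alpha_corrected = zc$alpha_corrected, effect_size_d = NA_real_,
      log10_bf10 = NA_real_, significant = zc$significant
    )
    if (!is.null(pfits)) {
      a <- pfits[pfits$phase == ct[1] & pfits$converged, ]
      b <- pfits[pfits$phase == ct[2] & pfits$converged, ]
      shared <- intersect(a$participant_id, b$participant_id)
      if (length(shared) >= 3) {
        tc <- t_compare(
          a$pse[match(shared, a$participant_id)],
          b$pse[match(shared, b$participant_id)],
          alpha = alpha, comparisons = k
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          contrast = paste(ct[1], "vs", ct[2]), statistic_kind = "paired_t",
          statistic = tc$statistic, df = tc$df, p_value = tc$p_value,
          alpha_corrected = tc$alpha_corrected,
          effect_size_d = tc$effect_size_d, log10_bf10 = tc$log10_bf10,
          significant = tc$significant
        )
      }
    }
  }

  bundle <- structure(
    list(
      fits = fit_table(trials, grouping = "aggregate", reference = reference),
      participant_fits = pfits,
      bootstrap = tibble::tibble(
        phase = names(boots),
        mean_peak = vapply(boots, function(b) b$mean_peak, 0),
        se_peak = vapply(boots, function(b) b$se_peak, 0),
        n_iterations = vapply(boots, function(b) b$n_iterations, 0L),
        n_failed = vapply(boots, function(b) b$n_failed, 0L),
        seed = vapply(boots, function(b) b$seed, 0L)
      ),
      comparisons = dplyr::bind_rows(rows),
      provenance = list(
        seed = as.integer(seed), n_bootstrap = n_bootstrap, alpha = alpha,
        bonferroni_k = k,
        alpha_corrected = bonferroni_alpha(alpha, k),
        config_hash = if (!is.null(config)) config_hash(config) else NA_character_,
        package_version = as.character(utils::packageVersion("samediff"))
      )
    ),
    class = "report_bundle"
  )
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> %d phase fit(s), %d comparison row(s), alpha_corrected %.4g, seed %d\n",
    nrow(x$fits), nrow(x$comparisons),
    x$provenance$alpha_corrected, x$provenance$seed
  ))
  print(x$comparisons)
  invisible(x)
}

#' Write a report bundle to delimiter-separated files
#'
#' @param bundle A `report_bundle` from [cmd_compare()].
#' @param out_dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_report <- function(bundle, out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    fits = file.path(out_dir, "fits.csv"),
    bootstrap = file.path(out_dir, "bootstrap.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    provenance = file.path(out_dir, "provenance.yaml")
  )
  write.csv(bundle$fits, paths["fits"], row.names = FALSE)
  write.csv(bundle$bootstrap, paths["bootstrap"], row.names = FALSE)
  write.csv(bundle$comparisons, paths["comparisons"], row.names = FALSE)
  yaml::write_yaml(bundle$provenance, paths["provenance"])
  invisible(paths)
}

#' Parameter-recovery harness
#'
#' Simulates `n_replicates` independent cohorts from a configuration,
#' fits the aggregate psychometric function per measurement phase, and
#' tabulates recovered against generative values: the true PSE of each
#' phase is `reference / gain`, so recovery error directly audits the whole
#' simulate-aggregate-fit pipeline.
#'
#' @param config A [run_config()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Root seed (one derived seed per replicate).
#' @return A list with `table` (one row per replicate x phase: true gain,
#'   true PSE, fitted PSE/Wf/R^2, signed error in percent of the true PSE)
#'   and `summary` (per phase: mean bias percent and RMSE in stimulus
#'   units).
#' @export
cmd_recover <- function(config, n_replicates = 20, seed = 1) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  plan <- config_plan(config)
  obs <- config_observer(config)
  reference <- plan$stimuli$reference
  seeds <- derive_seeds(seed, n_replicates)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cohort <- cohort_params(
      config$n_participants, config$between_subject_sd,
      seed = seeds[r]
    )
    trials <- simulate_cohort(plan, cohort, obs)
    for (ph in plan$measurement_phases) {
      fit <- suppressWarnings(
        fit_gaussian(aggregate_proportions(trials, phase = ph))
      )
      g <- phase_gain(obs, ph)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r, phase = ph, true_gain = g,
        true_pse = reference / g,
        fitted_pse = fit$pse, fitted_wf = fit$weber_fraction,
        r_squared = fit$r_squared, converged = fit$converged,
        error_percent = (fit$pse - reference / g) / (reference / g) * 100
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  summary <- tab |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      true_pse = .data$true_pse[1],
      mean_fitted_pse = mean(.data$fitted_pse),
      bias_percent = mean(.data$error_percent),
      rmse = sqrt(mean((.data$fitted_pse - .data$true_pse)^2)),
      n_converged = dplyr::n(),
      .groups = "drop"
    )
  list(table = tab, summary = summary)
}

#' Steps-per-second descriptive
#'
#' Converts a step count over a running bout into a cadence. The canonical
#' 8-minute bout (3-minute warm-up plus 5-minute test) with 1185.5 steps
#' gives 2.47 steps per second.
#'
#' @param n_steps Total steps during the bout.
#' @param duration_s Bout duration in seconds (default 480).
#' @return Steps per second.
#' @export
steps_per_second <- function(n_steps, duration_s = 480) {
  check_positive(duration_s, "duration_s")
  if (any(n_steps < 0)) abort_invalid("`n_steps` must be >= 0.")
  n_steps / duration_s
}
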