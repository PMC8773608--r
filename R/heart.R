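#' Heart-rate trace parameters
#'
#' The running protocol drives heart rate from rest to a target (80% of the
#' age-predicted maximum, see [target_heart_rate()]) over a 3-minute
#' warm-up ramp, then holds it near the target for a 5-minute plateau.
#' Defaults reflect the study-scale values: resting 87.06 bpm, target
#' 150.9 bpm.
#'
#' @param resting_hr Resting heart rate, bpm.
#' @param target_hr Exercise target heart rate, bpm; must exceed `resting_hr`.
#' @param ramp_duration Warm-up ramp length in seconds (default 180).
#' @param plateau_duration Plateau length in seconds (default 300).
#' @param trace_noise_sd Sample-to-sample Gaussian noise, bpm.
#' @param sampling_rate Samples per second (default 1 Hz).
#' @return A `heart_trace_params` object.
#' @export
heart_trace_params <- function(resting_hr = 87.06, target_hr = 150.9,
                               ramp_duration = 180, plateau_duration = 300,
                               trace_noise_sd = 2, sampling_rate = 1) {
  resting_hr <- check_positive(resting_hr, "resting_hr")
  target_hr <- check_positive(target_hr, "target_hr")
  if (target_hr <= resting_hr) abort_invalid("`target_hr` must exceed `resting_hr`.")
  ramp_duration <- check_positive(ramp_duration, "ramp_duration")
  plateau_duration <- check_positive(plateau_duration, "plateau_duration")
  if (trace_noise_sd < 0) abort_invalid("`trace_noise_sd` must be >= 0.")
  sampling_rate <- check_positive(sampling_rate, "sampling_rate")
  structure(
    list(
      resting_hr = resting_hr, target_hr = target_hr,
      ramp_duration = ramp_duration, plateau_duration = plateau_duration,
      trace_noise_sd = trace_noise_sd, sampling_rate = sampling_rate
    ),
    class = "heart_trace_params"
  )
}

#' Simulate a heart-rate trace for one running bout
#'
#' The noise-free trace rises from `resting_hr` as a saturating exponential,
#' `target - (target - resting) * exp(-3.5 t / ramp_duration)`, which starts
#' exactly at the resting rate and closes to within 2% of the target by the
#' end of the ramp; from the ramp end onward the mean sits at the target
#' (stationary plateau). Independent Gaussian noise is added per sample.
#'
#' @param params A [heart_trace_params()] object.
#' @param seed Integer seed for the noise.
#' @return A tibble with `t_s` (seconds since running onset) and `hr_bpm`,
#'   of length `(ramp_duration + plateau_duration) * sampling_rate`.
#' @export
simulate_heart_trace <- function(params = heart_trace_params(), seed = 1) {
  if (!inherits(params, "heart_trace_params")) {
    abort_invalid("`params` must be a heart_trace_params object.")
  }
  n <- as.integer((params$ramp_duration + params$plateau_duration) *
    params$sampling_rate)
  t <- (seq_len(n) - 1L) / params$sampling_rate
  span <- params$target_hr - params$resting_hr
  mean_hr <- ifelse(
    t < params$ramp_duration,
    params$target_hr - span * exp(-3.5 * t / params$ramp_duration),
    params$target_hr
  )
  noise <- if (params$trace_noise_sd > 0) {
    withr::with_seed(as.integer(seed), rnorm(n, 0, params$trace_noise_sd))
  } else {
    0
  }
  tibble::tibble(t_s = t, hr_bpm = mean_hr + noise)
}
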