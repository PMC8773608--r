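# Internal helpers shared across modules.

#' @noRd
abort_invalid <- function(msg, class = "samediff_invalid_argument") {
  rlang::abort(msg, class = c(class, "samediff_error"))
}

# round half away from zero; base round() is round-half-even
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic child seeds from one root seed; all < 2^31
#' @noRd
derive_seeds <- function(root_seed, n) {
  withr::with_seed(as.integer(root_seed), sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

#' @noRd
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive number.", name))
  }
  as.numeric(x)
}

# rolling 31-bit polynomial hash of a character scalar, for config provenance
#' @noRd
text_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @noRd
log_info <- function(...) {
  message("[samediff] ", sprintf(...))
}

# canonical trial-table columns shared by the simulator and all readers
#' @noRd
trial_table_columns <- function() {
  c(
    "participant_id", "experiment_kind", "block", "phase", "trial_index",
    "test_magnitude", "response", "seconds_since_phase_start"
  )
}

#' @noRd
check_trial_table <- function(trials) {
  missing_cols <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0(
        "Trial table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = c("samediff_schema_error", "samediff_error"),
      missing_columns = missing_cols
    )
  }
  bad <- setdiff(unique(trials$response), c("same", "different"))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("`response` must be 'same' or 'different'; found: ",
             paste(bad, collapse = ", ")),
      class = c("samediff_schema_error", "samediff_error")
    )
  }
  invisible(trials)
}
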