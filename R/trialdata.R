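#' Trial-level data: reading, validation, and trial-time alignment
#'
#' A trial table holds one row per completed change-detection trial:
#' `observer_id` (character), `session` (positive integer), `condition`
#' (`"post"` or `"retro"`), `trial_time` (1-based index within each
#' observer-by-condition series, in presentation order), `outcome` (0 =
#' incorrect, 1 = correct), and optionally `changed` (whether the probed item
#' was rotated) and `rt_ms`. The two interleaved conditions are treated as
#' parallel sequences: trial time 100 is the 100th post-cue trial or the 100th
#' retro-cue trial of that observer.
#'
#' @name trial-data
NULL

required_trial_cols <- c("observer_id", "session", "condition", "trial_time", "outcome")
optional_trial_cols <- c("changed", "rt_ms")

#' Validate a trial table
#'
#' Checks column presence and types, binary outcomes, condition labels, that
#' every observer has both conditions, and that within each
#' observer-by-condition series the trial times are exactly `1..N` with no
#' gaps or duplicates. The first offending row is named in the error.
#'
#' @param trials A data frame of trials (see [trial-data]).
#' @return The validated trials as a tibble, ordered by observer, condition
#'   and trial time, invisibly usable in a pipe.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(required_trial_cols, names(trials))
  if (length(missing_cols) > 0) {
    abort(sprintf("Trial table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "cuecurve_format_error")
  }
  trials <- tibble::as_tibble(trials)
  trials$observer_id <- as.character(trials$observer_id)
  trials$condition <- as.character(trials$condition)

  bad_cond <- which(!trials$condition %in% c("post", "retro"))
  if (length(bad_cond) > 0) {
    abort(sprintf("Row %d: condition must be 'post' or 'retro' (got '%s').",
                  bad_cond[1], trials$condition[bad_cond[1]]),
          class = "cuecurve_validation_error")
  }
  bad_out <- which(!trials$outcome %in% c(0, 1))
  if (length(bad_out) > 0) {
    abort(sprintf("Row %d: outcome must be 0 or 1 (got %s).",
                  bad_out[1], format(trials$outcome[bad_out[1]])),
          class = "cuecurve_validation_error")
  }
  bad_tt <- which(is.na(trials$trial_time) | trials$trial_time < 1 |
                    trials$trial_time != as.integer(trials$trial_time))
  if (length(bad_tt) > 0) {
    abort(sprintf("Row %d: trial_time must be a positive integer.", bad_tt[1]),
          class = "cuecurve_validation_error")
  }
  trials$trial_time <- as.integer(trials$trial_time)
  trials$outcome <- as.integer(trials$outcome)

  # Per-series index check: exactly 1..N, order-insensitive in the file.
  trials <- dplyr::arrange(trials, .data$observer_id, .data$condition, .data$trial_time)
  grp <- dplyr::group_by(trials, .data$observer_id, .data$condition)
  chk <- dplyr::summarise(
    grp,
    dup = .data$trial_time[which(duplicated(.data$trial_time))[1]],
    gap = setdiff(seq_len(max(.data$trial_time)), .data$trial_time)[1],
    .groups = "drop"
  )
  bad_dup <- which(!is.na(chk$dup))
  if (length(bad_dup) > 0) {
    i <- bad_dup[1]
    abort(sprintf("Observer '%s', condition '%s': duplicate trial_time %d.",
                  chk$observer_id[i], chk$condition[i], chk$dup[i]),
          class = "cuecurve_validation_error")
  }
  bad_gap <- which(!is.na(chk$gap))
  if (length(bad_gap) > 0) {
    i <- bad_gap[1]
    abort(sprintf("Observer '%s', condition '%s': gap in trial_time at %d.",
                  chk$observer_id[i], chk$condition[i], chk$gap[i]),
          class = "cuecurve_validation_error")
  }

  n_cond <- tapply(trials$condition, trials$observer_id,
                   function(x) length(unique(x)))
  one_sided <- names(n_cond)[n_cond < 2]
  if (length(one_sided) > 0) {
    abort(sprintf("Observer '%s' lacks records in both conditions.", one_sided[1]),
          class = "cuecurve_validation_error")
  }
  trials
}

#' Largest trial time covered by every observer in both conditions
#'
#' @param trials A validated trial table.
#' @return A single integer: the minimum over observer-by-condition series of
#'   the maximum trial time, i.e. the last trial time with data from everyone.
#' @export
common_length <- function(trials) {
  lens <- dplyr::summarise(
    dplyr::group_by(trials, .data$observer_id, .data$condition),
    n = max(.data$trial_time), .groups = "drop"
  )
  min(lens$n)
}

#' Read a canonical trial CSV
#'
#' The canonical format is a UTF-8 comma-separated file with header
#' `observer_id,session,condition,trial_time,outcome[,changed,rt_ms]` and
#' condition literals exactly `post` / `retro`. Rows may appear in any order;
#' trial times are stored explicitly and validated on read.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of trials ordered by observer, condition and
#'   trial time.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cuecurve_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        locale = readr::locale(decimal_mark = "."))
  validate_trials(df)
}

#' Write a trial table to the canonical CSV
#'
#' @param trials A validated trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0) trials <- validate_trials(trials)
  keep <- intersect(c(required_trial_cols, optional_trial_cols), names(trials))
  readr::write_csv(trials[, keep, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Truncate all series to a common trial-time range
#'
#' Cuts every observer-by-condition series at
#' `min(common_length(trials), limit)`, so that all series have identical
#' length afterwards (the analysis window ends at the last trial time with
#' data from every observer; the study design analyses trial times 1..1587
#' for cohorts whose per-condition lengths range from 1587 upwards).
#'
#' @param trials A validated trial table.
#' @param limit Optional positive integer, a further upper bound on trial time.
#' @return The truncated trial table; idempotent.
#' @export
align_and_truncate <- function(trials, limit = NULL) {
  trials <- validate_trials(trials)
  cut <- common_length(trials)
  if (!is.null(limit)) {
    stopifnot_scalar_int(limit, "limit")
    cut <- min(cut, as.integer(limit))
  }
  dplyr::filter(trials, .data$trial_time <= cut)
}
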