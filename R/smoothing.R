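#' Edge-shrinking centered moving average over binary outcomes
#'
#' Converts a 0/1 outcome sequence into a continuous accuracy series. The
#' value at trial `t` is the arithmetic mean of outcomes in
#' `[t - h(t), t + h(t)]` with half-width `h(t) = min(window/2, t - 1, N - t)`:
#' in the series interior the window is a centered span of `window + 1` trials
#' (including the current trial), and it shrinks symmetrically towards both
#' ends so that no value is extrapolated. Values within `window/2` of either
#' end are computed normally but rest on fewer trials and should be read with
#' caution; [smooth_trials()] flags them.
#'
#' The moving average acts as a low-pass filter: small windows expose fast
#' accuracy fluctuations (mostly attentional noise), large windows expose the
#' slow learning curve.
#'
#' @param outcomes Numeric vector of 0/1 outcomes, length >= 1.
#' @param window Nominal full window width: a positive even integer, the
#'   number of neighbouring trials averaged in the interior (half on each
#'   side of the current trial).
#' @return Numeric vector of accuracies in `[0, 1]`, same length as
#'   `outcomes`.
#' @examples
#' moving_average(c(1, 0, 1, 0, 1), window = 4)
#' @export
moving_average <- function(outcomes, window) {
  n <- length(outcomes)
  if (n == 0) abort("`outcomes` must have length >= 1.")
  if (anyNA(outcomes) || !is_binary(outcomes)) {
    abort("`outcomes` must be a binary (0/1) sequence.",
          class = "cuecurve_validation_error")
  }
  window <- stopifnot_scalar_int(window, "window", min = 2L)
  if (window %% 2 != 0) abort("`window` must be an even integer.")
  half <- window %/% 2
  t <- seq_len(n)
  h <- pmin(half, t - 1L, n - t)
  cs <- c(0, cumsum(outcomes))
  (cs[t + h + 1L] - cs[t - h]) / (2 * h + 1)
}

#' Caution margin of a smoothing window
#'
#' Leading/trailing span (in trials) over which the centered window was
#' shrunk: `window / 2`.
#'
#' @param window Positive even integer window width.
#' @return Integer margin.
#' @export
caution_margin <- function(window) {
  window <- stopifnot_scalar_int(window, "window", min = 2L)
  window %/% 2L
}

#' Smooth every observer-by-condition outcome series
#'
#' Applies [moving_average()] to each observer-by-condition series of a trial
#' table.
#'
#' @param trials A validated trial table (see [trial-data]).
#' @param window Positive even integer window width (defaults to 200, the
#'   width used for the headline analyses).
#' @return A tibble with columns `observer_id`, `condition`, `trial_time`,
#'   `accuracy`, `window`, and logical `caution` marking trial times within
#'   `window/2` of either end of the series.
#' @export
smooth_trials <- function(trials, window = 200) {
  trials <- validate_trials(trials)
  margin <- caution_margin(window)
  out <- dplyr::reframe(
    dplyr::group_by(trials, .data$observer_id, .data$condition),
    trial_time = .data$trial_time,
    accuracy = moving_average(.data$outcome, window),
    caution = .data$trial_time <= margin |
      .data$trial_time > (max(.data$trial_time) - margin)
  )
  out$window <- as.integer(window)
  tibble::as_tibble(out[, c("observer_id", "condition", "trial_time",
                            "accuracy", "window", "caution")])
}
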