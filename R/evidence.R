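#' Sequential evidence for a retro-cue benefit
#'
#' At each trial time the package reports a standardized effect size between
#' conditions and a default Bayes factor for the benefit being greater than
#' zero. The effect size is
#' \deqn{d = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2) / 2},}
#' a pooled-by-average-variance Cohen's d. The Bayes factor places a standard
#' Cauchy prior (a Student's t with one degree of freedom) on the effect
#' size, truncated to positive effects, and compares the marginal likelihood
#' of the one-sample t statistic of the paired per-observer differences
#' against the point null.
#'
#' @name evidence
NULL

#' Standardized effect size between two conditions
#'
#' `d = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)`. Reduces to classical
#' Cohen's d when the two SDs are equal; antisymmetric in the two conditions.
#'
#' @param mu1,sigma1 Mean and SD of the first condition.
#' @param mu2,sigma2 Mean and SD of the second condition.
#' @return Numeric effect size(s).
#' @export
effect_size <- function(mu1, sigma1, mu2, sigma2) {
  if (any(sigma1 < 0 | sigma2 < 0)) {
    abort("SDs must be non-negative.", class = "cuecurve_argument_error")
  }
  denom <- sqrt((sigma1^2 + sigma2^2) / 2)
  if (any(denom == 0)) {
    abort("Effect size undefined: both SDs are zero.",
          class = "cuecurve_undefined_effect_error")
  }
  (mu1 - mu2) / denom
}

half_cauchy_density <- function(delta, scale) {
  2 / (pi * scale * (1 + (delta / scale)^2))
}

#' Directional default Bayes factor from a one-sample t statistic
#'
#' Evidence for an effect size `delta > 0` against the point null
#' `delta = 0`, with `delta ~ Cauchy(0, scale)` truncated to positive values
#' (the default one-sided JZS prior). The marginal likelihood
#' `integral of f(t | df = n - 1, ncp = delta * sqrt(n)) * prior(delta)` is
#' computed by adaptive quadrature with relative tolerance `1e-6`.
#'
#' @param t_stat One-sample t statistic(s) of the paired differences.
#' @param n Number of paired observations (>= 2).
#' @param scale Cauchy prior scale (default 1, the standard Cauchy).
#' @param side Only `"greater"` is defined: evidence for a positive effect.
#' @return Numeric vector of Bayes factors `bf10 > 0`; values below 1 favor
#'   the null.
#' @examples
#' bayes_factor_directional(3, n = 10)
#' @export
bayes_factor_directional <- function(t_stat, n, scale = 1,
                                     side = "greater") {
  side <- match.arg(side, "greater")
  if (n < 2) abort("`n` must be >= 2.", class = "cuecurve_argument_error")
  if (scale <= 0) abort("`scale` must be positive.",
                        class = "cuecurve_argument_error")
  df <- n - 1
  vapply(t_stat, function(t) {
    if (!is.finite(t)) return(if (is.na(t)) NA_real_ else if (t > 0) Inf else 0)
    num <- tryCatch(
      stats::integrate(
        function(delta) {
          suppressWarnings(stats::dt(t, df = df, ncp = delta * sqrt(n))) *
            half_cauchy_density(delta, scale)
        },
        lower = 0, upper = Inf, rel.tol = 1e-6, abs.tol = 0,
        subdivisions = 500L
      ),
      error = function(e) {
        abort(sprintf("Bayes factor quadrature failed at t = %.4g (n = %d): %s",
                      t, n, conditionMessage(e)),
              class = "cuecurve_numeric_error")
      }
    )
    num$value / stats::dt(t, df = df)
  }, numeric(1))
}

#' Per-trial-time evidence trace
#'
#' For every trial time, computes the paired per-observer differences of
#' smoothed accuracy (retro minus post), their one-sample t statistic, the
#' standardized effect size of [evidence], and the directional Bayes factor
#' [bayes_factor_directional()]. Consecutive Bayes factors are descriptive
#' and not corrected for multiplicity.
#'
#' @param smoothed A [smooth_trials()] table with both conditions; every
#'   observer must cover the full trial-time range.
#' @param group Optional [estimate_groups()] table; when supplied, the effect
#'   size uses the posterior group means and between-observer SDs, otherwise
#'   the per-observer sample means and SDs per condition.
#' @param scale Cauchy prior scale for the Bayes factor.
#' @param source `"observers"` (default) computes the t statistic from the
#'   per-observer smoothed differences; `"group"` derives it from the
#'   group-model effect size as `d * sqrt(n)`.
#' @return A tibble with `trial_time`, `d`, `t_stat`, `bf10`, `n_obs`.
#' @export
evidence_trace <- function(smoothed, group = NULL, scale = 1,
                           source = c("observers", "group")) {
  source <- match.arg(source)
  wide <- tidyr::pivot_wider(
    smoothed[, c("observer_id", "condition", "trial_time", "accuracy")],
    names_from = "condition", values_from = "accuracy"
  )
  if (anyNA(wide$retro) || anyNA(wide$post)) {
    abort("Every observer must cover the full trial-time range in both conditions.",
          class = "cuecurve_estimation_error")
  }
  wide$diff <- wide$retro - wide$post
  by_t <- dplyr::summarise(
    dplyr::group_by(wide, .data$trial_time),
    n_obs = dplyr::n(),
    mean_diff = mean(.data$diff),
    sd_diff = stats::sd(.data$diff),
    mu_retro = mean(.data$retro), sd_retro = stats::sd(.data$retro),
    mu_post = mean(.data$post), sd_post = stats::sd(.data$post),
    .groups = "drop"
  )
  if (any(by_t$n_obs < 2)) {
    abort("Evidence trace needs at least 2 observers.",
          class = "cuecurve_estimation_error")
  }

  if (is.null(group)) {
    denom <- sqrt((by_t$sd_retro^2 + by_t$sd_post^2) / 2)
    d <- ifelse(denom > 0, (by_t$mu_retro - by_t$mu_post) / denom,
                ifelse(by_t$mu_retro == by_t$mu_post, 0, NA_real_))
  } else {
    g <- dplyr::arrange(group, .data$condition, .data$trial_time)
    retro <- g[g$condition == "retro", ]
    post <- g[g$condition == "post", ]
    if (!identical(retro$trial_time, by_t$trial_time) ||
        !identical(post$trial_time, by_t$trial_time)) {
      abort("`group` must cover the same trial times as `smoothed`.",
            class = "cuecurve_argument_error")
    }
    d <- effect_size(retro$mu, retro$sigma_between,
                     post$mu, post$sigma_between)
  }

  n <- by_t$n_obs
  if (source == "observers") {
    t_stat <- ifelse(
      by_t$sd_diff > 0,
      by_t$mean_diff / (by_t$sd_diff / sqrt(n)),
      ifelse(by_t$mean_diff == 0, 0, sign(by_t$mean_diff) * 100)
    )
  } else {
    t_stat <- d * sqrt(n)
  }
  bf10 <- bayes_factor_directional(t_stat, n = n[1], scale = scale)
  tibble::tibble(trial_time = by_t$trial_time, d = d, t_stat = t_stat,
                 bf10 = bf10, n_obs = n)
}

#' First sustained Bayes-factor threshold crossing
#'
#' The smallest trial time from which `bf10 >= threshold` holds for at least
#' `persistence` consecutive trials. The persistence requirement
#' operationalizes "reliably crosses": momentary excursions above the
#' threshold do not count.
#'
#' @param trace An [evidence_trace()] tibble (columns `trial_time`, `bf10`).
#' @param threshold Bayes-factor threshold (default 3, the conventional
#'   "evidence worth considering" mark).
#' @param persistence Minimum run length in trials (default 50).
#' @return The crossing trial time, or `NA` if the trace never sustains the
#'   threshold.
#' @export
first_crossing <- function(trace, threshold = 3, persistence = 50) {
  if (nrow(trace) == 0) abort("`trace` is empty.", class = "cuecurve_argument_error")
  stopifnot_scalar_int(persistence, "persistence")
  trace <- dplyr::arrange(trace, .data$trial_time)
  above <- trace$bf10 >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= persistence)
  if (length(ok) == 0) return(NA_integer_)
  trace$trial_time[starts[ok[1]]]
}
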