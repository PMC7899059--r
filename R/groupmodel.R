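#' Hierarchical group model for smoothed accuracy
#'
#' At each trial time and condition, the smoothed accuracy values of the
#' observers are modelled as draws from a population:
#' \deqn{y_i \sim \mathrm{Normal}(\mu, \sigma^2),\quad
#'       \mu \sim \mathrm{Normal}(0.5, 0.5^2)\ \mathrm{truncated\ to}\ [0,1],\quad
#'       \sigma \sim \mathrm{Half\text{-}Normal}(0, 0.5^2).}
#' Posterior summaries are obtained by Gibbs sampling (the \eqn{\mu} step is
#' an exact truncated-normal draw; the \eqn{\sigma} step is a random-walk
#' Metropolis update on \eqn{\log\sigma}). Estimation is independent per trial
#' time — temporal structure is already supplied by the smoothing step.
#'
#' @name group-model
NULL

default_group_prior <- function() {
  list(mu_mean = 0.5, mu_sd = 0.5, sigma_scale = 0.5)
}

# Vectorized Gibbs over the rows of Y (one row = one trial-time x condition
# cell, columns = observers). Returns posterior summaries per row; optionally
# the mu draw matrix (draws x rows) for draw-level checks.
gibbs_group_matrix <- function(Y, prior = default_group_prior(),
                               draws = 4000, warmup = 1000, seed = 1,
                               return_draws = FALSE, mh_step = 0.35) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  n <- ncol(Y)
  if (n < 2) abort("Group estimation needs at least 2 observers.",
                   class = "cuecurve_estimation_error")
  ybar <- rowMeans(Y)
  prior_prec <- 1 / prior$mu_sd^2
  prior_mean <- prior$mu_mean
  sig_scale2 <- prior$sigma_scale^2

  mu <- ybar
  s0 <- sqrt(pmax(apply(Y, 1, stats::var), 1e-6))
  log_sig <- log(s0)
  # floor on sigma: identical observer values would otherwise let log-sigma
  # random-walk to -Inf and collapse the mu posterior to a point
  log_sig_floor <- log(1e-5)

  sum_mu <- numeric(m); sum_mu2 <- numeric(m)
  sum_sig <- numeric(m); sum_sig2 <- numeric(m)
  mu_draws <- if (return_draws) matrix(NA_real_, draws, m)

  # log target for sigma given mu (log-sigma parameterization incl. Jacobian)
  sig_logpost <- function(ls, ss) {
    sig2 <- exp(2 * ls)
    -n * ls - ss / (2 * sig2) - sig2 / (2 * sig_scale2) + ls
  }

  with_substream(seed, "group", 0L, {
    total <- warmup + draws
    for (it in seq_len(total)) {
      sig2 <- exp(2 * log_sig)
      post_prec <- n / sig2 + prior_prec
      post_var <- 1 / post_prec
      post_mean <- post_var * (n * ybar / sig2 + prior_prec * prior_mean)
      post_sd <- sqrt(post_var)
      # exact truncated-normal draw on [0, 1] by inverse CDF
      lo <- stats::pnorm(0, post_mean, post_sd)
      hi <- stats::pnorm(1, post_mean, post_sd)
      u <- lo + stats::runif(m) * (hi - lo)
      mu <- stats::qnorm(clip(u, 1e-12, 1 - 1e-12), post_mean, post_sd)

      ss <- rowSums((Y - mu)^2)
      prop <- log_sig + stats::rnorm(m, 0, mh_step)
      log_acc <- sig_logpost(prop, ss) - sig_logpost(log_sig, ss)
      accept <- log(stats::runif(m)) < log_acc & prop >= log_sig_floor
      log_sig[accept] <- prop[accept]

      if (it > warmup) {
        sig <- exp(log_sig)
        dmu <- mu - ybar  # centred accumulation avoids cancellation
        sum_mu <- sum_mu + dmu
        sum_mu2 <- sum_mu2 + dmu^2
        sum_sig <- sum_sig + sig
        sum_sig2 <- sum_sig2 + sig^2
        if (return_draws) mu_draws[it - warmup, ] <- mu
      }
    }
  })

  dbar <- sum_mu / draws
  mu_hat <- ybar + dbar
  se_mu <- sqrt(pmax(sum_mu2 / draws - dbar^2, 0))
  sig_hat <- sum_sig / draws
  out <- tibble::tibble(mu = mu_hat, sigma_between = sig_hat, se_mu = se_mu,
                        n_obs = n)
  if (return_draws) attr(out, "mu_draws") <- mu_draws
  out
}

#' Posterior group estimate at one trial time
#'
#' Fits the hierarchical normal model (see [group-model]) to the accuracy
#' values of `>= 2` observers at a single trial time.
#'
#' @param values Numeric vector of per-observer accuracy values.
#' @param prior List with `mu_mean`, `mu_sd` (truncated-normal hyperprior on
#'   the population mean) and `sigma_scale` (half-normal scale of the
#'   between-observer SD).
#' @param draws,warmup Posterior draws kept after warm-up.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return One-row tibble with `mu` (posterior mean of the population mean),
#'   `sigma_between` (posterior mean of the between-observer SD), `se_mu`
#'   (posterior SD of the population mean) and `n_obs`.
#' @export
estimate_group <- function(values, prior = default_group_prior(),
                           draws = 4000, warmup = 1000, seed = 1) {
  if (length(values) < 2) {
    abort("Group estimation needs at least 2 observers.",
          class = "cuecurve_estimation_error")
  }
  gibbs_group_matrix(matrix(values, nrow = 1), prior = prior, draws = draws,
                     warmup = warmup, seed = seed)
}

#' Group estimates for every trial time and condition
#'
#' Runs the hierarchical model of [group-model] independently at every trial
#' time of each condition of a smoothed table. All trial-time cells are
#' updated in one vectorized Gibbs pass, so the cost is essentially that of a
#' single chain.
#'
#' @param smoothed Output of [smooth_trials()]; every observer must cover the
#'   full common trial-time range in both conditions (see
#'   [align_and_truncate()]).
#' @inheritParams estimate_group
#' @return A tibble with `condition`, `trial_time`, `mu`, `sigma_between`,
#'   `se_mu`, `n_obs`.
#' @export
estimate_groups <- function(smoothed, prior = default_group_prior(),
                            draws = 4000, warmup = 1000, seed = 1) {
  wide <- tidyr::pivot_wider(
    smoothed[, c("observer_id", "condition", "trial_time", "accuracy")],
    names_from = "observer_id", values_from = "accuracy"
  )
  Y <- as.matrix(wide[, setdiff(names(wide), c("condition", "trial_time"))])
  if (anyNA(Y)) {
    abort("All observers must cover the full trial-time range; run align_and_truncate() first.",
          class = "cuecurve_estimation_error")
  }
  est <- gibbs_group_matrix(Y, prior = prior, draws = draws, warmup = warmup,
                            seed = seed)
  out <- dplyr::bind_cols(wide[, c("condition", "trial_time")], est)
  dplyr::arrange(out, .data$condition, .data$trial_time)
}

#' Retro-cue benefit trace
#'
#' Elementwise difference of the estimated group means (retro minus post) per
#' trial time, with uncertainty propagated as
#' `sqrt(se_retro^2 + se_post^2)`.
#'
#' @param group Output of [estimate_groups()] containing both conditions, or
#'   the retro-condition estimates alone if `post` is supplied.
#' @param post Optional post-condition estimates when `group` holds only the
#'   retro condition.
#' @param scale `"accuracy"` (default) or `"k"`; on the `k` scale the benefit
#'   and its SE are multiplied by `2 * set_size` per Cowan's relation.
#' @param set_size Memory array size, used only for `scale = "k"`.
#' @return A tibble with `trial_time`, `benefit`, `se`, `scale`.
#' @export
benefit_trace <- function(group, post = NULL, scale = c("accuracy", "k"),
                          set_size = 12) {
  scale <- match.arg(scale)
  if (is.null(post)) {
    retro <- dplyr::filter(group, .data$condition == "retro")
    post <- dplyr::filter(group, .data$condition == "post")
  } else {
    retro <- group
  }
  retro <- dplyr::arrange(retro, .data$trial_time)
  post <- dplyr::arrange(post, .data$trial_time)
  if (nrow(retro) == 0 || nrow(post) == 0 ||
      !identical(retro$trial_time, post$trial_time)) {
    abort("Retro and post estimates must cover identical trial-time ranges.",
          class = "cuecurve_argument_error")
  }
  fac <- if (scale == "k") 2 * set_size else 1
  tibble::tibble(
    trial_time = retro$trial_time,
    benefit = (retro$mu - post$mu) * fac,
    se = sqrt(retro$se_mu^2 + post$se_mu^2) * fac,
    scale = scale
  )
}

#' Cowan's k from single-probe change-detection accuracy
#'
#' The capacity estimate `k = (2 * accuracy - 1) * set_size`: the number of
#' array items an observer would need to hold perfectly to produce the
#' observed accuracy, with guessing at chance on the rest. Chance accuracy
#' (0.5) maps to `k = 0`; below-chance accuracy yields negative `k`.
#'
#' @param accuracy Proportion correct in `[0, 1]`.
#' @param set_size Number of items in the memory array (positive integer).
#' @return A tibble with `accuracy`, `set_size`, `k_items`.
#' @examples
#' cowan_k(0.75, 12) # k = 6
#' @export
cowan_k <- function(accuracy, set_size) {
  if (any(accuracy < 0 | accuracy > 1)) {
    abort("`accuracy` must lie in [0, 1].", class = "cuecurve_argument_error")
  }
  stopifnot_scalar_int(set_size, "set_size")
  tibble::tibble(accuracy = accuracy, set_size = as.integer(set_size),
                 k_items = (2 * accuracy - 1) * set_size)
}

#' Accuracy implied by a Cowan's k capacity
#'
#' Exact inverse of [cowan_k()]: `accuracy = (k / set_size + 1) / 2`.
#'
#' @param k_items Capacity in items, `|k_items| <= set_size`.
#' @param set_size Number of items in the memory array.
#' @return Numeric vector of proportions correct.
#' @examples
#' accuracy_from_k(16, 32) # 0.75
#' @export
accuracy_from_k <- function(k_items, set_size) {
  stopifnot_scalar_int(set_size, "set_size")
  if (any(abs(k_items) > set_size)) {
    abort("`|k_items|` cannot exceed `set_size`.", class = "cuecurve_argument_error")
  }
  (k_items / set_size + 1) / 2
}
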