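#' Growth models for the retro-cue benefit
#'
#' Three candidate descriptions of how the benefit develops over trial time
#' `x`:
#' \itemize{
#'   \item linear: `m * x + c` (parameters `m`, `c`);
#'   \item exponential: `a * exp(-k * x) + c` (parameters `k`, `a`, `c`);
#'   \item logistic: `l1 + (l0 - l1) / (1 + (x / x0)^k)` (parameters `k`,
#'     `x0` the inflection point, `l0` the lower and `l1` the upper
#'     asymptote).
#' }
#' Models are fitted by least squares and ranked by the Bayesian information
#' criterion `BIC = -2 * LL + ln(N) * k`, where `LL` is the Gaussian
#' log-likelihood at the maximum-likelihood residual variance and `k` counts
#' the curve parameters only (2/3/4). Lower (more negative) BIC is better.
#'
#' @name growth-models
NULL

curve_n_params <- c(linear = 2L, exponential = 3L, logistic = 4L)

#' Evaluate a growth model
#'
#' @param params Named numeric vector (or list) of parameters: `m`, `c`
#'   (linear); `a`, `k`, `c` (exponential); `l0`, `l1`, `x0`, `k` (logistic).
#'   A [fit_curve()] result may be passed directly.
#' @param x Trial times; must be positive for the logistic model.
#' @param model One of `"linear"`, `"exponential"`, `"logistic"`; taken from
#'   `params` when it is a fit object.
#' @return Numeric vector of curve values.
#' @export
curve_value <- function(params, x, model = NULL) {
  if (inherits(params, "cue_fit")) {
    model <- params$model
    params <- params$params
  }
  p <- as.list(params)
  model <- match.arg(model, c("linear", "exponential", "logistic"))
  switch(model,
    linear = p$m * x + p$c,
    exponential = p$a * exp(-p$k * x) + p$c,
    logistic = {
      if (any(x <= 0)) abort("Logistic curve requires x > 0.",
                             class = "cuecurve_argument_error")
      if (p$x0 <= 0) abort("Logistic `x0` must be positive.",
                           class = "cuecurve_argument_error")
      logistic_curve(x, p$l0, p$l1, p$x0, p$k)
    }
  )
}

# Gaussian log-likelihood of a least-squares fit at the MLE residual variance.
gauss_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi * max(rss, 1e-300) / n) + 1)
}

new_cue_fit <- function(model, params, x, y, degenerate = FALSE,
                        convergence = 0L) {
  fitted <- curve_value(params, x, model)
  rss <- sum((y - fitted)^2)
  n <- length(y)
  k <- curve_n_params[[model]]
  ll <- gauss_loglik(rss, n)
  structure(
    list(model = model, params = params, rss = rss, loglik = ll,
         n_points = n, n_params = k, bic = -2 * ll + log(n) * k,
         fitted = fitted, x = x, degenerate = degenerate,
         convergence = convergence),
    class = "cue_fit"
  )
}

# Least squares with a linear basis; returns coefficients or NULL on failure.
lin_solve <- function(B, y) {
  fit <- tryCatch(stats::lm.fit(B, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  fit$coefficients
}

fit_linear_ls <- function(x, y) {
  cf <- lin_solve(cbind(x = x, `(Intercept)` = 1), y)
  c(m = unname(cf[1]), c = unname(cf[2]))
}

# Exponential a*exp(-k*x)+c is linear in (a, c) given k: profile the RSS over
# k on a log grid, then refine with golden-section search.
fit_exponential_ls <- function(x, y, n_grid = 40) {
  rng <- diff(range(x))
  grid <- exp(seq(log(0.1 / rng), log(50 / rng), length.out = n_grid))
  prss <- function(k) {
    cf <- lin_solve(cbind(exp(-k * x), 1), y)
    if (is.null(cf)) return(Inf)
    sum((cf[1] * exp(-k * x) + cf[2] - y)^2)
  }
  vals <- vapply(grid, prss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(function(lk) prss(exp(lk)), c(log(lo), log(hi)),
                         tol = 1e-10)
  k <- exp(opt$minimum)
  if (prss(grid[i]) < opt$objective) k <- grid[i]
  cf <- lin_solve(cbind(exp(-k * x), 1), y)
  c(k = k, a = unname(cf[1]), c = unname(cf[2]))
}

# Logistic: linear in (l1, l0 - l1) given (x0, k); profile over (log x0,
# log k) with a deterministic multistart grid plus a data-driven start
# (l0/l1 from the trace ends, x0 at the half-rise, k = 3).
fit_logistic_ls <- function(x, y, l_bounds = NULL, n_starts = 8) {
  n <- length(x)
  if (is.null(l_bounds)) l_bounds <- c(-0.5, 0.5)
  basis_rss <- function(lx0, lk) {
    g <- 1 / (1 + (x / exp(lx0))^exp(lk))
    cf <- lin_solve(cbind(1, g), y)
    if (is.null(cf)) return(list(rss = Inf))
    l1 <- clip(cf[1], l_bounds[1], l_bounds[2])
    l0 <- clip(cf[1] + cf[2], l_bounds[1], l_bounds[2])
    list(rss = sum((l1 + (l0 - l1) * g - y)^2),
         par = c(l0 = unname(l0), l1 = unname(l1)))
  }
  obj <- function(p) basis_rss(p[1], p[2])$rss

  head_m <- mean(y[seq_len(max(1, round(0.05 * n)))])
  tail_m <- mean(y[seq(n - max(1, round(0.05 * n)) + 1, n)])
  half <- head_m + 0.5 * (tail_m - head_m)
  x_half <- x[which.min(abs(y - half))]
  starts <- rbind(
    expand.grid(lx0 = log(stats::quantile(x, c(0.02, 0.05, 0.1, 0.2, 0.35,
                                               0.5, 0.75))),
                lk = log(c(0.5, 1.5, 3, 6))),
    data.frame(lx0 = log(max(x_half, 1)), lk = log(3))
  )
  lower <- c(log(1), log(1e-3)); upper <- c(log(max(x)), log(20))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    p0 <- clip(as.numeric(starts[j, ]), lower, upper)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-14 ||
        (abs(res$value - best$value) <= 1e-14 &&
         res$counts[1] < best$counts[1])) {
      best <- res
    }
  }
  if (is.null(best)) {
    abort("Logistic fit failed to converge from any start.",
          class = "cuecurve_fit_error")
  }
  sol <- basis_rss(best$par[1], best$par[2])
  c(sol$par, x0 = unname(exp(best$par[1])), k = unname(exp(best$par[2])))
}

#' Fit one growth model to a benefit trace by least squares
#'
#' Linear fits use the closed-form solution; exponential and logistic fits
#' profile their conditionally linear parameters and search the remaining
#' nonlinear ones over a deterministic multistart grid, so repeated fits are
#' bit-identical. A constant trace fitted with the logistic model returns a
#' flat curve flagged as degenerate.
#'
#' @param trace A [benefit_trace()] tibble (columns `trial_time`, `benefit`),
#'   or any data frame with those columns.
#' @param model `"linear"`, `"exponential"`, or `"logistic"`.
#' @param l_bounds Bounds for the logistic asymptotes; defaults to
#'   `[-0.5, 0.5]` accuracy units, widened automatically for traces on other
#'   scales.
#' @return A `cue_fit` object: parameters, `rss`, Gaussian `loglik`, `bic`
#'   (`-2 LL + ln(N) k` with `k` the curve-parameter count), and fitted
#'   values. Use [tidy()] / [glance()] to extract tibbles.
#' @export
fit_curve <- function(trace, model = c("linear", "exponential", "logistic"),
                      l_bounds = NULL) {
  model <- match.arg(model)
  x <- as.numeric(trace$trial_time)
  y <- as.numeric(trace$benefit)
  if (length(x) < curve_n_params[[model]] + 1) {
    abort("Trace shorter than n_params + 1.", class = "cuecurve_argument_error")
  }
  if (model == "logistic" && stats::sd(y) < 1e-12) {
    return(new_cue_fit("logistic",
                       c(l0 = mean(y), l1 = mean(y), x0 = max(x) / 2, k = 1),
                       x, y, degenerate = TRUE))
  }
  params <- switch(model,
    linear = fit_linear_ls(x, y),
    exponential = fit_exponential_ls(x, y),
    logistic = fit_logistic_ls(x, y, l_bounds = l_bounds)
  )
  new_cue_fit(model, params, x, y)
}

#' @export
print.cue_fit <- function(x, ...) {
  cat(sprintf("<cue_fit: %s>\n", x$model))
  print(round(x$params, 6))
  cat(sprintf("N = %d, RSS = %.6g, logLik = %.2f, BIC = %.2f%s\n",
              x$n_points, x$rss, x$loglik, x$bic,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cue_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method generics::glance
glance.cue_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, loglik = x$loglik,
                 bic = x$bic, n_points = x$n_points, n_params = x$n_params,
                 degenerate = isTRUE(x$degenerate))
}

#' Compare the three growth models by BIC
#'
#' Fits the linear, exponential and logistic models to a benefit trace and
#' prefers the minimum-BIC model. When per-observer smoothed data are
#' supplied, a leave-one-observer-out robustness analysis re-runs group
#' estimation, the benefit trace, and all three fits with each observer
#' removed in turn, tallying which model each permutation prefers.
#'
#' @param trace A [benefit_trace()] tibble.
#' @param smoothed Optional [smooth_trials()] tibble with both conditions,
#'   enabling the leave-one-out analysis.
#' @param loo Run the leave-one-observer-out analysis (requires `smoothed`).
#' @param draws,warmup,prior,seed Group-model settings for the leave-one-out
#'   re-estimation (see [estimate_groups()]).
#' @return A `cue_comparison` object: `fits` (named list of `cue_fit`),
#'   `table` (one row per model with BIC and delta-BIC), `preferred`, and
#'   when requested `loo` (per-left-out-observer BICs and preference) and
#'   `preference_counts`.
#' @export
compare_models <- function(trace, smoothed = NULL, loo = !is.null(smoothed),
                           draws = 4000, warmup = 1000,
                           prior = default_group_prior(), seed = 1) {
  models <- c("linear", "exponential", "logistic")
  fits <- list()
  errors <- list()
  for (m in models) {
    f <- tryCatch(fit_curve(trace, m), error = function(e) e)
    if (inherits(f, "error")) errors[[m]] <- conditionMessage(f) else fits[[m]] <- f
  }
  if (length(fits) == 0) abort("All model fits failed.", class = "cuecurve_fit_error")
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab$delta_bic <- tab$bic - min(tab$bic)
  preferred <- tab$model[order(tab$bic, tab$rss)][1]

  loo_tab <- NULL
  pref_counts <- NULL
  if (loo) {
    if (is.null(smoothed)) {
      abort("Leave-one-out requires the per-observer `smoothed` table.",
            class = "cuecurve_argument_error")
    }
    obs <- sort(unique(smoothed$observer_id))
    loo_tab <- purrr::map_dfr(obs, function(o) {
      sub <- dplyr::filter(smoothed, .data$observer_id != o)
      grp <- estimate_groups(sub, prior = prior, draws = draws,
                             warmup = warmup, seed = seed)
      tr <- benefit_trace(grp)
      bics <- vapply(models, function(m) {
        f <- tryCatch(fit_curve(tr, m), error = function(e) NULL)
        if (is.null(f)) NA_real_ else f$bic
      }, numeric(1))
      tibble::tibble(left_out = o,
                     bic_linear = bics[["linear"]],
                     bic_exponential = bics[["exponential"]],
                     bic_logistic = bics[["logistic"]],
                     preferred = models[which.min(bics)])
    })
    pref_counts <- dplyr::count(loo_tab, .data$preferred, name = "n")
  }

  structure(
    list(fits = fits, table = tab, preferred = preferred,
         loo = loo_tab, preference_counts = pref_counts,
         fit_errors = if (length(errors)) errors),
    class = "cue_comparison"
  )
}

#' @export
print.cue_comparison <- function(x, ...) {
  cat("<cue_comparison>\n")
  print(as.data.frame(x$table[, c("model", "rss", "bic", "delta_bic")]))
  cat(sprintf("preferred: %s\n", x$preferred))
  if (!is.null(x$preference_counts)) {
    cat("leave-one-observer-out preferences:\n")
    print(as.data.frame(x$preference_counts))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cue_comparison <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.cue_comparison <- function(x, ...) {
  tibble::tibble(
    preferred = x$preferred,
    delta_bic_runner_up = sort(x$table$delta_bic)[2],
    loo_agreement = if (is.null(x$loo)) NA_real_ else
      mean(x$loo$preferred == x$preferred)
  )
}

#' Plateau point of a fitted logistic benefit curve
#'
#' The smallest trial time at which the magnitude of the analytic first
#' derivative of the fitted logistic falls below `rate_threshold` and stays
#' below it. Computed by bisection on the decreasing tail of the derivative;
#' the search is bounded at `10 * N` trials. A curve whose derivative never
#' exceeds the threshold returns trial 1 flagged flat. The derivative is
#' invariant to vertical shifts of the curve.
#'
#' @param fit A logistic `cue_fit`.
#' @param rate_threshold Benefit change per trial below which the curve is
#'   considered flat; may be a vector. The defaults `1e-4` and `1e-5`
#'   correspond to accuracy changes of 0.01% and 0.001% per trial.
#' @return A tibble with one row per threshold: `rate_threshold`,
#'   `trial_time`, `flat` (derivative never exceeded the threshold),
#'   `unreached` (still above threshold at the search bound).
#' @export
plateau_point <- function(fit, rate_threshold = c(1e-4, 1e-5)) {
  if (!inherits(fit, "cue_fit") || fit$model != "logistic") {
    abort("`fit` must be a logistic cue_fit.", class = "cuecurve_argument_error")
  }
  p <- as.list(fit$params)
  amp <- abs(p$l1 - p$l0)
  dmag <- function(x) {
    u <- x / p$x0
    amp * p$k * u^(p$k - 1) / (p$x0 * (1 + u^p$k)^2)
  }
  x_max <- 10 * fit$n_points
  purrr::map_dfr(rate_threshold, function(thr) {
    if (thr <= 0) abort("`rate_threshold` must be positive.",
                        class = "cuecurve_argument_error")
    if (amp < 1e-15 || p$k <= 0) {
      return(tibble::tibble(rate_threshold = thr, trial_time = 1,
                            flat = TRUE, unreached = FALSE))
    }
    # derivative peaks at x0 * ((k-1)/(k+1))^(1/k) for k > 1, at 0+ otherwise
    x_peak <- if (p$k > 1) p$x0 * ((p$k - 1) / (p$k + 1))^(1 / p$k) else 1
    x_peak <- clip(x_peak, 1, x_max)
    if (max(dmag(x_peak), dmag(1)) < thr) {
      return(tibble::tibble(rate_threshold = thr, trial_time = 1,
                            flat = TRUE, unreached = FALSE))
    }
    if (dmag(x_max) >= thr) {
      return(tibble::tibble(rate_threshold = thr, trial_time = x_max,
                            flat = FALSE, unreached = TRUE))
    }
    lo <- x_peak; hi <- x_max
    while (hi - lo > 1e-6 * max(1, lo)) {
      mid <- (lo + hi) / 2
      if (dmag(mid) >= thr) lo <- mid else hi <- mid
    }
    tibble::tibble(rate_threshold = thr, trial_time = (lo + hi) / 2,
                   flat = FALSE, unreached = FALSE)
  })
}

#' Late-phase linear trend of a trace
#'
#' Ordinary least-squares slope per trial, with its 95% confidence interval,
#' on a trial-time window of a group mean (or benefit) series. Mirrors the
#' exploratory check of whether accuracy is still rising late in practice.
#'
#' @param series A data frame with `trial_time` and a value column, or a bare
#'   numeric vector indexed by trial time.
#' @param from,to Window bounds (inclusive trial times), `from < to`.
#' @param value Name of the value column when `series` is a data frame
#'   (default `"mu"`, falling back to `"benefit"` if absent).
#' @return One-row tibble: `slope`, `se`, `conf.low`, `conf.high`, `from`,
#'   `to`, `n`.
#' @export
late_trend <- function(series, from, to, value = NULL) {
  if (is.data.frame(series)) {
    value <- value %||% if ("mu" %in% names(series)) "mu" else "benefit"
    tt <- series$trial_time
    y <- series[[value]]
  } else {
    tt <- seq_along(series)
    y <- as.numeric(series)
  }
  keep <- tt >= from & tt <= to
  if (from >= to || sum(keep) < 3) {
    abort("Trend window must contain at least 3 points with from < to.",
          class = "cuecurve_argument_error")
  }
  fit <- stats::lm(y[keep] ~ tt[keep])
  # exact lines (zero residual) are valid input; silence the perfect-fit note
  ci <- suppressWarnings(stats::confint(fit, 2, level = 0.95))
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(slope = unname(stats::coef(fit)[2]), se = sm[2, 2],
                 conf.low = ci[1], conf.high = ci[2],
                 from = from, to = to, n = sum(keep))
}
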