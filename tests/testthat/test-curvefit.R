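test_that("curve_value evaluates the three model equations exactly", {
  expect_equal(curve_value(c(m = 0, c = 0.083), c(1, 10, 1000), "linear"),
               rep(0.083, 3))
  expect_equal(curve_value(c(a = 1, k = log(2), c = 0), 1, "exponential"), 0.5)
  # logistic asymptote algebra: l0 near zero, l1 far out
  p <- c(l0 = 0, l1 = 0.083, x0 = 100, k = 2)
  expect_lt(curve_value(p, 1e-9, "logistic"), 1e-10)
  expect_equal(curve_value(p, 1e9, "logistic"), 0.083, tolerance = 1e-6)
  expect_equal(curve_value(p, 100, "logistic"), 0.083 / 2)
  expect_error(curve_value(p, -1, "logistic"), class = "cuecurve_argument_error")
})

test_that("noiseless data recover generating parameters to high accuracy", {
  x <- 1:1587
  lin <- tibble::tibble(trial_time = x, benefit = 1e-4 * x + 0.01)
  fl <- fit_curve(lin, "linear")
  expect_equal(unname(fl$params), c(1e-4, 0.01), tolerance = 1e-8)

  truth_e <- c(a = -0.083, k = 0.01, c = 0.083)
  ye <- curve_value(truth_e, x, "exponential")
  fe <- fit_curve(tibble::tibble(trial_time = x, benefit = ye), "exponential")
  expect_equal(fe$params[names(truth_e)], truth_e, tolerance = 1e-4)

  truth_l <- c(l0 = 0, l1 = 0.083, x0 = 150, k = 3)
  yl <- curve_value(truth_l, x, "logistic")
  flog <- fit_curve(tibble::tibble(trial_time = x, benefit = yl), "logistic")
  expect_equal(flog$params[c("l1", "x0", "k")], truth_l[c("l1", "x0", "k")],
               tolerance = 1e-4)
  expect_lt(abs(flog$params[["l0"]]), 1e-4 * 0.083)
})

test_that("BIC identity holds to machine precision and ranks by parameter count on pure noise", {
  set.seed(12)
  x <- 1:400
  y <- curve_value(c(l0 = 0, l1 = 0.08, x0 = 80, k = 3), x, "logistic") +
    rnorm(400, 0, 0.01)
  for (m in c("linear", "exponential", "logistic")) {
    f <- fit_curve(tibble::tibble(trial_time = x, benefit = y), m)
    expect_equal(f$bic, -2 * f$loglik + log(f$n_points) * f$n_params,
                 tolerance = 1e-12)
    expect_gte(f$rss, 0)
  }
})

test_that("fitting is deterministic", {
  set.seed(13)
  x <- 1:300
  y <- curve_value(c(l0 = -0.01, l1 = 0.09, x0 = 60, k = 2), x, "logistic") +
    rnorm(300, 0, 0.02)
  tr <- tibble::tibble(trial_time = x, benefit = y)
  f1 <- fit_curve(tr, "logistic")
  f2 <- fit_curve(tr, "logistic")
  expect_identical(f1, f2)
})

test_that("a constant trace yields a degenerate flagged logistic fit", {
  tr <- tibble::tibble(trial_time = 1:50, benefit = rep(0.05, 50))
  f <- fit_curve(tr, "logistic")
  expect_true(f$degenerate)
  expect_equal(f$params[["l0"]], f$params[["l1"]])
  expect_error(fit_curve(tr[1:3, ], "logistic"), class = "cuecurve_argument_error")
})

test_that("accuracy-scale and k-scale fits agree up to the linear transform", {
  set.seed(14)
  x <- 1:500
  y <- curve_value(c(l0 = 0, l1 = 0.083, x0 = 100, k = 3), x, "logistic") +
    rnorm(500, 0, 0.005)
  S <- 12
  fa <- fit_curve(tibble::tibble(trial_time = x, benefit = y), "logistic")
  fk <- fit_curve(tibble::tibble(trial_time = x, benefit = y * 2 * S), "logistic",
                  l_bounds = c(-0.5, 0.5) * 2 * S)
  expect_equal(fk$params[["l1"]], fa$params[["l1"]] * 2 * S, tolerance = 1e-3)
  expect_equal(fk$params[["x0"]], fa$params[["x0"]], tolerance = 1e-2)
  expect_equal(fk$params[["k"]], fa$params[["k"]], tolerance = 1e-2)
})

test_that("compare_models selects the minimum-BIC model and tallies LOO", {
  tr <- small_cohort(seed = 15, n_observers = 4, trials = 200,
                     benefit = list(shape = "logistic", l0 = 0, l1 = 0.15,
                                    x0 = 40, k = 3))
  sm <- smooth_trials(tr, 50)
  g <- estimate_groups(sm, draws = 400, warmup = 150, seed = 2)
  b <- benefit_trace(g)
  cmp <- compare_models(b, smoothed = sm, loo = TRUE, draws = 300,
                        warmup = 100, seed = 2)
  expect_setequal(tidy(cmp)$model, c("linear", "exponential", "logistic"))
  expect_equal(cmp$preferred,
               cmp$table$model[which.min(cmp$table$bic)])
  expect_equal(sum(cmp$preference_counts$n), 4)
  expect_equal(min(cmp$table$delta_bic), 0)
})

test_that("plateau point matches a dense grid scan and respects its invariances", {
  x <- 1:1587
  truth <- c(l0 = 0, l1 = 0.083, x0 = 150, k = 3)
  f <- fit_curve(tibble::tibble(
    trial_time = x, benefit = curve_value(truth, x, "logistic")), "logistic")
  p <- plateau_point(f, 1e-4)
  # independent dense numerical scan of |f'(x)|
  grid <- seq(1, 10 * 1587, by = 0.25)
  fx <- curve_value(f, grid)
  dnum <- abs(diff(fx) / diff(grid))
  peak_i <- which.max(dnum)
  below <- which(dnum < 1e-4 & seq_along(dnum) > peak_i)
  expect_lt(abs(p$trial_time - grid[below[1]]), 1)

  # halving the threshold never yields an earlier plateau
  p2 <- plateau_point(f, c(1e-4, 5e-5, 1e-5))
  expect_true(all(diff(p2$trial_time) >= -1e-6))

  # vertical shifts leave the plateau unchanged
  shifted <- f
  shifted$params[c("l0", "l1")] <- shifted$params[c("l0", "l1")] + 0.2
  expect_equal(plateau_point(shifted, 1e-4)$trial_time, p$trial_time)

  # flat curve flags
  flat <- f
  flat$params[["l1"]] <- flat$params[["l0"]]
  pf <- plateau_point(flat, 1e-4)
  expect_true(pf$flat)
  expect_equal(pf$trial_time, 1)
})

test_that("late trends recover exact lines and are linear in the series", {
  t <- 1:1587
  lt <- late_trend(tibble::tibble(trial_time = t, mu = 6.2e-5 * t + 0.6),
                   500, 1587)
  expect_equal(lt$slope, 6.2e-5, tolerance = 1e-10)

  const <- late_trend(rep(0.7, 100), 10, 90)
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_true(const$conf.low <= 0 && const$conf.high >= 0)

  set.seed(16)
  a <- cumsum(rnorm(200, 0, 1e-3)) + 0.7
  b <- cumsum(rnorm(200, 0, 1e-3)) + 0.6
  s_diff <- late_trend(a - b, 50, 150)$slope
  expect_equal(s_diff, late_trend(a, 50, 150)$slope - late_trend(b, 50, 150)$slope,
               tolerance = 1e-12)
  expect_error(late_trend(a, 100, 101), class = "cuecurve_argument_error")
})
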