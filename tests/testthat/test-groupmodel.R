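test_that("degenerate equal-valued observers recover their common mean", {
  est <- estimate_group(rep(0.75, 10), seed = 1)
  expect_equal(est$mu, 0.75, tolerance = 1e-3)
  expect_lt(est$sigma_between, 0.05)
})

test_that("posterior mean and SE agree with the conjugate closed form", {
  # three observers: the scaled-t posterior has df = 2, so only the location
  # comparison is meaningful at this size
  vals3 <- c(0.6, 0.7, 0.8)
  est3 <- estimate_group(vals3, prior = list(mu_mean = 0.5, mu_sd = 5,
                                             sigma_scale = 5),
                         draws = 8000, warmup = 2000, seed = 2)
  expect_lt(abs(est3$mu - oracle_conjugate_mu(vals3)$mean), 2 * est3$se_mu)

  # ten observers: both location and spread must match the closed form
  vals10 <- c(0.55, 0.62, 0.71, 0.68, 0.60, 0.74, 0.66, 0.59, 0.70, 0.63)
  est10 <- estimate_group(vals10, prior = list(mu_mean = 0.5, mu_sd = 5,
                                               sigma_scale = 5),
                          draws = 8000, warmup = 2000, seed = 2)
  ora <- oracle_conjugate_mu(vals10)
  expect_lt(abs(est10$mu - ora$mean), 2 * est10$se_mu)
  expect_lt(abs(est10$mu - ora$mean), 0.01)
  expect_lt(abs(est10$se_mu - ora$se) / ora$se, 0.25)
})

test_that("estimation is deterministic given the seed and stable across seeds", {
  vals <- c(0.55, 0.62, 0.71, 0.68, 0.60, 0.74, 0.66, 0.59, 0.70, 0.63)
  a <- estimate_group(vals, seed = 7)
  b <- estimate_group(vals, seed = 7)
  expect_identical(a, b)
  c <- estimate_group(vals, seed = 8)
  expect_lt(abs(a$mu - c$mu), 1e-3)
})

test_that("mu approaches the sample mean as hyperpriors flatten", {
  vals <- c(0.52, 0.61, 0.66, 0.72, 0.58)
  est <- estimate_group(vals, prior = list(mu_mean = 0.5, mu_sd = 50,
                                           sigma_scale = 50),
                        draws = 20000, warmup = 2000, seed = 3)
  expect_equal(est$mu, mean(vals), tolerance = 2e-3)
})

test_that("fewer than two observers is an estimation error", {
  expect_error(estimate_group(0.7), class = "cuecurve_estimation_error")
})

test_that("estimate_groups runs all trial-time cells and matches single-cell runs qualitatively", {
  tr <- small_cohort(seed = 6, n_observers = 4, trials = 40)
  sm <- smooth_trials(tr, 10)
  g <- estimate_groups(sm, draws = 500, warmup = 200, seed = 4)
  expect_equal(nrow(g), 80)
  expect_true(all(g$mu >= 0 & g$mu <= 1))
  expect_true(all(g$se_mu > 0))
  # posterior mean tracks the cross-observer sample mean
  wide <- tidyr::pivot_wider(sm[, c("observer_id", "condition", "trial_time", "accuracy")],
                             names_from = observer_id, values_from = accuracy)
  sample_means <- rowMeans(as.matrix(wide[, -(1:2)]))
  g2 <- dplyr::arrange(g, condition, trial_time)
  wide <- dplyr::arrange(wide, condition, trial_time)
  expect_lt(max(abs(g2$mu - sample_means)), 0.12)
})

test_that("benefit trace subtracts means and propagates SEs like paired draws", {
  tr <- small_cohort(seed = 9, n_observers = 6, trials = 30)
  sm <- smooth_trials(tr, 10)
  wide <- tidyr::pivot_wider(sm[, c("observer_id", "condition", "trial_time", "accuracy")],
                             names_from = observer_id, values_from = accuracy)
  Y <- as.matrix(wide[, -(1:2)])
  est <- cuecurve:::gibbs_group_matrix(Y, draws = 4000, warmup = 500, seed = 5,
                                       return_draws = TRUE)
  draws <- attr(est, "mu_draws")
  g <- dplyr::bind_cols(wide[, 1:2], est)
  b <- benefit_trace(g)
  is_retro <- wide$condition == "retro"
  diff_draws <- draws[, is_retro] - draws[, !is_retro]
  expect_equal(b$benefit, unname(colMeans(diff_draws)), tolerance = 1e-12)
  # independent-sampler SE propagation matches the draw-level SD within MC error
  expect_equal(b$se, unname(apply(diff_draws, 2, sd)), tolerance = 0.12)
})

test_that("benefit_trace is zero for identical inputs and errors on mismatch", {
  g <- tibble::tibble(condition = rep(c("post", "retro"), each = 3),
                      trial_time = rep(1:3, 2),
                      mu = rep(c(0.667, 0.75), each = 3),
                      se_mu = 0.01, sigma_between = 0.05, n_obs = 10)
  b <- benefit_trace(g)
  expect_equal(b$benefit, rep(0.083, 3))
  expect_equal(b$se, rep(sqrt(2) * 0.01, 3))
  same <- benefit_trace(g[g$condition == "retro", ], g[g$condition == "retro", ])
  expect_equal(same$benefit, rep(0, 3))
  expect_error(benefit_trace(g[g$condition == "retro", ],
                             g[g$condition == "post", ][1:2, ]),
               class = "cuecurve_argument_error")
})

test_that("Cowan's k transform and its inverse are exact and linear", {
  expect_equal(cowan_k(0.75, 32)$k_items, 16)
  expect_equal(cowan_k(0.75, 12)$k_items, 6)
  expect_equal(cowan_k(2 / 3, 12)$k_items, 4)
  expect_equal(cowan_k(0.5, 23)$k_items, 0)
  expect_equal(accuracy_from_k(16, 32), 0.75)
  expect_equal(accuracy_from_k(0, 9), 0.5)
  # linearity: delta k = 2 S delta accuracy; 2 items at S = 12 is 1/12
  expect_equal(cowan_k(0.667 + 1 / 12, 12)$k_items - cowan_k(0.667, 12)$k_items, 2)
  set.seed(11)
  a <- runif(1000)
  S <- 17
  expect_equal(accuracy_from_k(cowan_k(a, S)$k_items, S), a)
  expect_error(cowan_k(1.2, 12), class = "cuecurve_argument_error")
  expect_error(accuracy_from_k(13, 12), class = "cuecurve_argument_error")
})
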