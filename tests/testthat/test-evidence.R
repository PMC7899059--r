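test_that("effect size evaluates the pooled-by-average form exactly", {
  expect_equal(effect_size(0.8, 0.1, 0.7, 0.1), 1.0)
  expect_equal(effect_size(0.7, 0.2, 0.7, 0.05), 0)
  # antisymmetry
  set.seed(20)
  for (i in 1:20) {
    m <- runif(2); s <- runif(2, 0.01, 0.3)
    expect_equal(effect_size(m[1], s[1], m[2], s[2]),
                 -effect_size(m[2], s[2], m[1], s[1]))
  }
  # reduces to classical Cohen's d when SDs are equal
  expect_equal(effect_size(0.9, 0.12, 0.6, 0.12), (0.9 - 0.6) / 0.12)
  expect_error(effect_size(0.5, 0, 0.4, 0),
               class = "cuecurve_undefined_effect_error")
})

test_that("directional Bayes factor matches the fixed-grid quadrature oracle", {
  for (tv in c(-2, 0, 1, 3, 8)) {
    got <- bayes_factor_directional(tv, n = 10, scale = 1)
    ora <- oracle_bf_directional(tv, n = 10, scale = 1)
    expect_equal(got, ora, tolerance = 1e-3)
  }
  # smaller prior scale, other n
  expect_equal(bayes_factor_directional(2.5, n = 6, scale = sqrt(2) / 2),
               oracle_bf_directional(2.5, n = 6, scale = sqrt(2) / 2),
               tolerance = 1e-3)
})

test_that("Bayes factor behaves like a directional likelihood ratio", {
  expect_lt(bayes_factor_directional(0, n = 10), 1)
  expect_gt(bayes_factor_directional(8, n = 10), 100)
  tgrid <- seq(-3, 6, by = 0.5)
  bfs <- bayes_factor_directional(tgrid, n = 10)
  expect_true(all(diff(bfs) > 0))
  # one-sided halves recombine into the two-sided default BF
  t0 <- 2.2
  two_sided <- (oracle_bf_directional(t0, 10) + oracle_bf_directional(-t0, 10)) / 2
  halves <- (bayes_factor_directional(t0, 10) +
               bayes_factor_directional(-t0, 10)) / 2
  expect_equal(halves, two_sided, tolerance = 1e-3)
  expect_error(bayes_factor_directional(1, n = 1), class = "cuecurve_argument_error")
  expect_error(bayes_factor_directional(1, n = 10, scale = 0),
               class = "cuecurve_argument_error")
})

test_that("identical conditions give null evidence at every trial time", {
  tr <- small_cohort(seed = 22, n_observers = 5, trials = 60)
  sm <- smooth_trials(tr, 10)
  post <- sm[sm$condition == "post", ]
  mirrored <- dplyr::bind_rows(post, dplyr::mutate(post, condition = "retro"))
  ev <- evidence_trace(mirrored)
  expect_equal(ev$d, rep(0, 60))
  expect_true(all(ev$bf10 < 1))
})

test_that("doubling the cohort strengthens positive evidence", {
  tr <- small_cohort(seed = 23, n_observers = 6, trials = 80,
                     baseline = 0.55,
                     benefit = list(shape = "logistic", l0 = 0.25, l1 = 0.25,
                                    x0 = 10, k = 2))
  sm <- smooth_trials(tr, 20)
  doubled <- dplyr::bind_rows(
    sm, dplyr::mutate(sm, observer_id = paste0(observer_id, "_b")))
  ev1 <- evidence_trace(sm)
  ev2 <- evidence_trace(doubled)
  # clearly positive effects: at weak effects more nulls-favoring data can
  # legitimately shrink the Bayes factor
  pos <- which(ev1$t_stat > 2 & is.finite(ev1$bf10) & ev1$bf10 < 1e6)
  expect_true(length(pos) > 10)
  expect_true(all(ev2$bf10[pos] > ev1$bf10[pos]))
  # duplicating every observer doubles n; the t statistic grows by sqrt(2)
  # times the (duplication-corrected) sample-SD ratio
  n1 <- ev1$n_obs[1]
  sd_ratio <- sqrt(2 * (n1 - 1) / (2 * n1 - 1))
  expect_equal(ev2$t_stat[pos], ev1$t_stat[pos] * sqrt(2) / sd_ratio,
               tolerance = 1e-9)
})

test_that("first_crossing honours persistence and step traces", {
  step <- tibble::tibble(trial_time = 1:600,
                         bf10 = c(rep(1, 299), rep(10, 301)))
  expect_equal(first_crossing(step, 3, persistence = 50), 300L)
  low <- tibble::tibble(trial_time = 1:100, bf10 = rep(2, 100))
  expect_true(is.na(first_crossing(low, 3)))

  # raising persistence never yields an earlier crossing
  set.seed(24)
  for (i in 1:20) {
    bf <- rexp(400, 1 / 3)
    trc <- tibble::tibble(trial_time = 1:400, bf10 = bf)
    cr <- vapply(c(1, 5, 20, 60), function(p) {
      x <- first_crossing(trc, 3, p); if (is.na(x)) 1e9 else as.numeric(x)
    }, numeric(1))
    expect_true(all(diff(cr) >= 0))
  }
  expect_error(first_crossing(step, 3, persistence = 0), "integer")
})

test_that("group-sourced and observer-sourced traces agree on sign and order", {
  tr <- small_cohort(seed = 25, n_observers = 6, trials = 80)
  sm <- smooth_trials(tr, 20)
  g <- estimate_groups(sm, draws = 400, warmup = 150, seed = 3)
  ev_obs <- evidence_trace(sm, group = g)
  ev_grp <- evidence_trace(sm, group = g, source = "group")
  expect_equal(nrow(ev_obs), 80)
  expect_gt(cor(ev_obs$d, ev_grp$d), 0.99)
})
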