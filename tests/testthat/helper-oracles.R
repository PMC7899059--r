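# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the moving-average oracle is a double loop, the
# group-model oracle is the conjugate closed form under a Jeffreys prior, and
# the Bayes-factor oracle is a fixed-grid trapezoid quadrature.

# Brute-force edge-shrinking windowed mean: loop over indices, loop over the
# window, average.
oracle_moving_average <- function(outcomes, window) {
  n <- length(outcomes)
  half <- window / 2
  out <- numeric(n)
  for (t in seq_len(n)) {
    h <- min(half, t - 1, n - t)
    acc <- 0
    for (j in (t - h):(t + h)) acc <- acc + outcomes[j]
    out[t] <- acc / (2 * h + 1)
  }
  out
}

# Conjugate posterior for a normal mean with unknown variance under the
# Jeffreys prior p(mu, s2) ~ 1/s2: mu | y is a scaled-t centred at the sample
# mean with scale s/sqrt(n) and df n - 1.
oracle_conjugate_mu <- function(values) {
  n <- length(values)
  s <- sd(values)
  list(mean = mean(values), se = s / sqrt(n),
       post_sd = s / sqrt(n) * sqrt((n - 1) / (n - 3)))
}

# Fixed-grid trapezoid quadrature of the directional default Bayes factor,
# substituting delta = scale * tan(theta) to map (0, Inf) onto (0, pi/2).
oracle_bf_directional <- function(t_stat, n, scale = 1, n_grid = 20000) {
  df <- n - 1
  theta <- seq(1e-9, pi / 2 - 1e-9, length.out = n_grid)
  delta <- scale * tan(theta)
  # prior density times Jacobian d delta / d theta = scale / cos(theta)^2
  prior <- 2 / (pi * scale * (1 + (delta / scale)^2)) * scale / cos(theta)^2
  lik <- suppressWarnings(stats::dt(t_stat, df = df, ncp = delta * sqrt(n)))
  num <- sum((lik * prior)[-1] + (lik * prior)[-n_grid]) / 2 * diff(theta)[1]
  num / stats::dt(t_stat, df = df)
}

# Small valid trial table built in code: n_obs observers x 2 conditions x
# n_trials, outcomes from a fixed-probability Bernoulli stream.
make_trials <- function(n_obs = 2, n_trials = 3, p = 0.7, seed = 42) {
  set.seed(seed)
  expand_grid_df <- expand.grid(
    observer_id = sprintf("s%02d", seq_len(n_obs)),
    condition = c("post", "retro"),
    trial_time = seq_len(n_trials),
    stringsAsFactors = FALSE
  )
  expand_grid_df$session <- 1L
  expand_grid_df$outcome <- rbinom(nrow(expand_grid_df), 1, p)
  tibble::as_tibble(expand_grid_df[, c("observer_id", "session", "condition",
                                       "trial_time", "outcome")])
}

# Tiny simulated cohort for pipeline-level tests: small enough to keep the
# Gibbs and fitting stages fast.
small_cohort <- function(seed = 5, n_observers = 5, trials = 300, ...) {
  simulate_trials(sim_config(n_observers = n_observers,
                             trials_per_condition = trials, seed = seed, ...))
}
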