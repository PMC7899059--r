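#' Synthetic retro-cue change-detection cohorts
#'
#' Generates trial-level datasets with the statistical structure the analysis
#' assumes: a cohort of observers, two interleaved conditions proceeding as
#' parallel trial-time sequences, a slowly drifting baseline accuracy in both
#' conditions, and a retro-cue benefit that rises logistically over a few
#' hundred trials to a fixed asymptote. Outcomes are Bernoulli draws from the
#' per-trial generating probability; the ground-truth curves are attached for
#' parameter-recovery studies.
#'
#' The defaults emulate the study conditions that motivated the analysis:
#' 10 observers, 1600 trials per condition, set size 12, post-cue accuracy
#' starting at 0.62 and drifting up by 6.2e-5 per trial, a retro baseline
#' drift of 3.7e-5 per trial, and a logistic benefit with asymptote 0.083
#' (2 items of capacity at set size 12), inflection at trial 150 and
#' exponent 3. Observer heterogeneity is normal on the baseline and on the
#' benefit asymptote; probabilities are clipped to `[0.05, 0.99]` to avoid
#' degenerate Bernoulli streams while permitting below-chance stretches.
#'
#' @name synthetic-cohorts
NULL

#' Simulation configuration
#'
#' @param n_observers Number of observers (default 10).
#' @param trials_per_condition Trials per condition per observer (default
#'   1600).
#' @param set_size Memory array size (default 12).
#' @param baseline Post-cue accuracy at trial 1 (default 0.62).
#' @param drift_post Baseline accuracy drift per trial in the post condition
#'   (default 6.2e-5).
#' @param drift_retro Drift per trial of the retro condition's baseline
#'   component (default 3.7e-5); the benefit curve is added on top, so with
#'   these defaults the late-phase benefit declines at 2.5e-5 per trial.
#' @param benefit Benefit shape: `list(shape = "logistic", l0, l1, x0, k)`
#'   (default `l0 = 0, l1 = 0.083, x0 = 150, k = 3`),
#'   `list(shape = "linear", slope)`, or
#'   `list(shape = "exponential", a, k, c)` for misspecification scenarios.
#' @param observer_sd SD of the normal observer-level perturbations applied
#'   to the baseline and to the benefit asymptote (default 0.02).
#' @param x0_sd Optional SD of observer-level perturbations of the logistic
#'   inflection point, covering individual differences in learning speed
#'   (default 0: shared `x0`).
#' @param interleave_block Trials per condition per interleaving block
#'   (default 4: blocks of four post-cue and four retro-cue trials in random
#'   order).
#' @param n_sessions Number of experimental sessions the trials are divided
#'   into (default 8).
#' @param clip Two-element probability clipping bounds (default
#'   `c(0.05, 0.99)`).
#' @param seed Integer seed; expanded into per-observer substreams so adding
#'   observers never perturbs existing ones.
#' @return A `cue_sim_config` list.
#' @export
sim_config <- function(n_observers = 10, trials_per_condition = 1600,
                       set_size = 12, baseline = 0.62,
                       drift_post = 6.2e-5, drift_retro = 3.7e-5,
                       benefit = list(shape = "logistic", l0 = 0, l1 = 0.083,
                                      x0 = 150, k = 3),
                       observer_sd = 0.02, x0_sd = 0, interleave_block = 4,
                       n_sessions = 8, clip = c(0.05, 0.99), seed = 1) {
  stopifnot_scalar_int(n_observers, "n_observers", 2L)
  stopifnot_scalar_int(trials_per_condition, "trials_per_condition")
  stopifnot_scalar_int(set_size, "set_size")
  if (!benefit$shape %in% c("logistic", "linear", "exponential")) {
    abort("benefit$shape must be 'logistic', 'linear' or 'exponential'.")
  }
  structure(
    list(n_observers = as.integer(n_observers),
         trials_per_condition = as.integer(trials_per_condition),
         set_size = as.integer(set_size), baseline = baseline,
         drift_post = drift_post, drift_retro = drift_retro,
         benefit = benefit, observer_sd = observer_sd, x0_sd = x0_sd,
         interleave_block = as.integer(interleave_block),
         n_sessions = as.integer(n_sessions), clip = clip,
         seed = as.integer(seed)),
    class = "cue_sim_config"
  )
}

benefit_component <- function(benefit, t, l1_shift = 0, x0_shift = 0) {
  switch(benefit$shape,
    logistic = logistic_curve(t, benefit$l0, benefit$l1 + l1_shift,
                              max(benefit$x0 + x0_shift, 1), benefit$k),
    linear = (benefit$slope + l1_shift / max(t)) * t,
    exponential = benefit$a * exp(-benefit$k * t) + benefit$c + l1_shift
  )
}

#' Generating probability of a correct response
#'
#' The per-trial Bernoulli probability before sampling:
#' `p_post(t) = clip(baseline + shift + drift_post * t)` and
#' `p_retro(t) = clip(baseline + shift + drift_retro * t + benefit(t))`.
#'
#' @param config A [sim_config()].
#' @param t Trial time(s), `t >= 1`.
#' @param condition `"post"` or `"retro"`.
#' @param baseline_shift,l1_shift,x0_shift Observer-level effects (default 0:
#'   the population-average observer).
#' @return Numeric vector of probabilities in the clipping bounds.
#' @export
true_probability <- function(config, t, condition = c("post", "retro"),
                             baseline_shift = 0, l1_shift = 0, x0_shift = 0) {
  condition <- match.arg(condition)
  base <- config$baseline + baseline_shift
  p <- if (condition == "post") {
    base + config$drift_post * t
  } else {
    base + config$drift_retro * t +
      benefit_component(config$benefit, t, l1_shift, x0_shift)
  }
  clip(p, config$clip[1], config$clip[2])
}

#' Simulate a trial-level dataset
#'
#' Draws observer effects, builds the ground-truth probability curves, and
#' emits Bernoulli outcomes for every observer, condition, and trial time.
#' The interleaving design (blocks of `interleave_block` trials per condition
#' in random order) is realized as a `presentation_index` metadata column;
#' the analysis itself operates on per-condition trial times. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A validated trial tibble (see [trial-data]) with extra columns
#'   `changed` and `presentation_index`, and the ground-truth curves attached
#'   as the `"truth"` attribute (retrievable with [sim_truth()]).
#' @export
simulate_trials <- function(config) {
  if (!inherits(config, "cue_sim_config")) config <- do.call(sim_config, config)
  T_n <- config$trials_per_condition
  t <- seq_len(T_n)
  session <- pmin(ceiling(t * config$n_sessions / T_n), config$n_sessions)

  per_obs <- purrr::map(seq_len(config$n_observers), function(i) {
    with_substream(config$seed, "simulate", i, {
      b_shift <- stats::rnorm(1, 0, config$observer_sd)
      l1_shift <- stats::rnorm(1, 0, config$observer_sd)
      x0_shift <- if (config$x0_sd > 0) stats::rnorm(1, 0, config$x0_sd) else 0
      p_post <- true_probability(config, t, "post", b_shift, l1_shift, x0_shift)
      p_retro <- true_probability(config, t, "retro", b_shift, l1_shift, x0_shift)
      out_post <- stats::rbinom(T_n, 1, p_post)
      out_retro <- stats::rbinom(T_n, 1, p_retro)
      changed <- stats::rbinom(2 * T_n, 1, 0.5)
      # block-shuffled presentation order over interleaved conditions
      blk <- config$interleave_block
      n_blocks <- ceiling(T_n / blk)
      order_within <- unlist(lapply(seq_len(n_blocks), function(b) {
        sample(2 * blk)
      }))
      id <- sprintf("s%02d", i)
      trials <- tibble::tibble(
        observer_id = id,
        session = rep(session, 2),
        condition = rep(c("post", "retro"), each = T_n),
        trial_time = rep(t, 2),
        outcome = c(out_post, out_retro),
        changed = changed
      )
      blk_of <- (trials$trial_time - 1) %/% blk
      within <- (trials$trial_time - 1) %% blk + 1 +
        ifelse(trials$condition == "retro", blk, 0)
      trials$presentation_index <- as.integer(
        blk_of * 2 * blk + order_within[blk_of * 2 * blk + within]
      )
      truth <- tibble::tibble(
        observer_id = id,
        condition = rep(c("post", "retro"), each = T_n),
        trial_time = rep(t, 2),
        p = c(p_post, p_retro)
      )
      list(trials = trials, truth = truth)
    })
  })

  trials <- dplyr::bind_rows(purrr::map(per_obs, "trials"))
  trials <- dplyr::arrange(trials, .data$observer_id, .data$presentation_index)
  trials <- validate_trials(trials)
  attr(trials, "truth") <- dplyr::bind_rows(purrr::map(per_obs, "truth"))
  attr(trials, "sim_config") <- config
  trials
}

#' Ground-truth generating curves of a simulated dataset
#'
#' @param trials Output of [simulate_trials()].
#' @return Tibble with `observer_id`, `condition`, `trial_time`, `p`.
#' @export
sim_truth <- function(trials) {
  truth <- attr(trials, "truth")
  if (is.null(truth)) abort("No ground truth attached: not a simulated dataset.")
  truth
}

#' Write the ground-truth sidecar table of a simulated dataset
#'
#' @param trials Output of [simulate_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(trials, path) {
  readr::write_csv(sim_truth(trials), path, progress = FALSE)
  invisible(path)
}
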