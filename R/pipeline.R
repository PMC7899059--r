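#' One-call analysis pipeline
#'
#' Runs the full learning-curve analysis on a trial table (real or
#' simulated): validate, truncate to the common trial-time range, smooth each
#' observer-by-condition series, estimate the group posterior per trial time
#' and condition, form the benefit trace, compare growth models by BIC (with
#' leave-one-observer-out robustness), locate the plateau of the fitted
#' logistic, compute the per-trial evidence trace and its first sustained
#' Bayes-factor crossing, and fit late-phase linear trends. All numeric
#' output is reproducible bit-identically from (input, configuration, seed).
#'
#' @param trials A trial tibble (see [trial-data]) or a path to a canonical
#'   trial CSV.
#' @param window Moving-average window width (default 200 trials).
#' @param limit Optional truncation limit on trial time.
#' @param set_size Memory array size, for capacity transforms (default 12).
#' @param draws,warmup,prior Group-model settings (see [estimate_groups()]).
#' @param bf_threshold,persistence First-crossing rule for the evidence trace
#'   (defaults: Bayes factor 3 sustained for 50 trials).
#' @param plateau_thresholds Derivative thresholds in accuracy per trial
#'   (defaults `1e-4` and `1e-5`, i.e. 0.01% and 0.001% per trial).
#' @param late_from Start of the late-trend window (default trial 500;
#'   shortened to a third of the trace for short inputs).
#' @param loo Run the leave-one-observer-out model comparison (default TRUE).
#' @param seed Integer seed governing all sampling stages.
#' @param out_dir Optional directory: when given, all tables plus a
#'   human-readable summary are written there.
#' @param verbose Log each stage to stderr.
#' @return A `cue_report` object with elements `smoothed`, `group` (accuracy
#'   and capacity columns), `benefit`, `benefit_k`, `comparison`, `plateaus`,
#'   `evidence`, `first_crossing`, `late_trends`, and a `config` provenance
#'   block. Use [glance()] for a one-row summary.
#' @export
run_analysis <- function(trials, window = 200, limit = NULL, set_size = 12,
                         draws = 4000, warmup = 1000,
                         prior = default_group_prior(),
                         bf_threshold = 3, persistence = 50,
                         plateau_thresholds = c(1e-4, 1e-5),
                         late_from = 500, loo = TRUE, seed = 1,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(trials)) {
    say("read: %s", trials)
    trials <- read_trials(trials)
  }
  trials <- align_and_truncate(trials, limit)
  n_obs <- length(unique(trials$observer_id))
  T_n <- common_length(trials)
  say("aligned: %d observers, %d trial times per condition", n_obs, T_n)

  smoothed <- smooth_trials(trials, window = window)
  say("smoothed with window %d", window)

  group <- estimate_groups(smoothed, prior = prior, draws = draws,
                           warmup = warmup, seed = seed)
  group$k <- cowan_k(clip(group$mu, 0, 1), set_size)$k_items
  say("group model: %d cells, %d draws", nrow(group), draws)

  benefit <- benefit_trace(group)
  benefit_k <- benefit_trace(group, scale = "k", set_size = set_size)

  comparison <- compare_models(benefit, smoothed = if (loo) smoothed,
                               loo = loo, draws = draws, warmup = warmup,
                               prior = prior, seed = seed)
  say("model comparison: preferred %s", comparison$preferred)

  plateaus <- if ("logistic" %in% names(comparison$fits)) {
    plateau_point(comparison$fits$logistic, plateau_thresholds)
  }

  evidence <- evidence_trace(smoothed, group = group)
  crossing <- first_crossing(evidence, threshold = bf_threshold,
                             persistence = persistence)
  say("evidence: first sustained BF >= %g crossing at %s", bf_threshold,
      ifelse(is.na(crossing), "none", crossing))

  from_eff <- if (T_n >= late_from + 3) late_from else max(1, ceiling(T_n / 3))
  late <- dplyr::bind_rows(
    dplyr::mutate(late_trend(group[group$condition == "post", ], from_eff, T_n),
                  series = "post", .before = 1),
    dplyr::mutate(late_trend(group[group$condition == "retro", ], from_eff, T_n),
                  series = "retro", .before = 1),
    dplyr::mutate(late_trend(benefit, from_eff, T_n, value = "benefit"),
                  series = "benefit", .before = 1)
  )

  report <- structure(
    list(smoothed = smoothed, group = group, benefit = benefit,
         benefit_k = benefit_k, comparison = comparison, plateaus = plateaus,
         evidence = evidence, first_crossing = crossing, late_trends = late,
         config = list(window = window, limit = limit, set_size = set_size,
                       draws = draws, warmup = warmup, prior = prior,
                       bf_threshold = bf_threshold, persistence = persistence,
                       plateau_thresholds = plateau_thresholds,
                       late_from = from_eff, loo = loo, seed = seed,
                       n_obs = n_obs, common_length = T_n,
                       version = as.character(utils::packageVersion("cuecurve")))),
    class = "cue_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write all report tables to a directory
#'
#' Emits `smoothed.csv`, `group.csv`, `benefit.csv`, `models.csv`,
#' `evidence.csv` and a human-readable `summary.txt`, so that every figure of
#' the analysis can be reconstructed from the tables.
#'
#' @param report A `cue_report`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) readr::write_csv(df, file.path(out_dir, f), progress = FALSE)
  w(report$smoothed, "smoothed.csv")
  w(report$group, "group.csv")
  w(dplyr::bind_rows(report$benefit, report$benefit_k), "benefit.csv")
  models <- report$comparison$table
  models$preferred <- models$model == report$comparison$preferred
  w(models, "models.csv")
  w(report$evidence, "evidence.csv")
  writeLines(utils::capture.output(print(report)), file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.cue_report <- function(x, ...) {
  cfg <- x$config
  cat("<cue_report>\n")
  cat(sprintf("  %d observers, trial times 1..%d, window %d, seed %d (v%s)\n",
              cfg$n_obs, cfg$common_length, cfg$window, cfg$seed, cfg$version))
  cat(sprintf("  preferred growth model: %s\n", x$comparison$preferred))
  for (m in x$comparison$table$model) {
    row <- x$comparison$table[x$comparison$table$model == m, ]
    cat(sprintf("    %-11s BIC %10.1f  (dBIC %6.1f)\n", m, row$bic, row$delta_bic))
  }
  if (!is.null(x$comparison$preference_counts)) {
    pc <- x$comparison$preference_counts
    cat(sprintf("  leave-one-out preferences: %s\n",
                paste(sprintf("%s=%d", pc$preferred, pc$n), collapse = ", ")))
  }
  if (!is.null(x$plateaus)) {
    for (i in seq_len(nrow(x$plateaus))) {
      cat(sprintf("  plateau (|slope| < %g/trial): trial %.0f%s\n",
                  x$plateaus$rate_threshold[i], x$plateaus$trial_time[i],
                  ifelse(x$plateaus$flat[i], " [flat]", "")))
    }
  }
  fit <- x$comparison$fits$logistic
  if (!is.null(fit)) {
    cat(sprintf("  logistic benefit asymptote: %.4f accuracy (= %.2f items at set size %d)\n",
                fit$params[["l1"]] - fit$params[["l0"]],
                (fit$params[["l1"]] - fit$params[["l0"]]) * 2 * cfg$set_size,
                cfg$set_size))
  }
  cat(sprintf("  first sustained BF >= %g crossing: %s\n", cfg$bf_threshold,
              ifelse(is.na(x$first_crossing), "none", x$first_crossing)))
  for (i in seq_len(nrow(x$late_trends))) {
    r <- x$late_trends[i, ]
    cat(sprintf("  late trend [%d..%d] %-8s slope %+.3g [%+.3g, %+.3g]\n",
                r$from, r$to, paste0(r$series, ":"), r$slope, r$conf.low, r$conf.high))
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cue_report <- function(x, ...) {
  fit <- x$comparison$fits$logistic
  asym <- if (is.null(fit)) NA_real_ else fit$params[["l1"]] - fit$params[["l0"]]
  tibble::tibble(
    preferred = x$comparison$preferred,
    asymptote = asym,
    asymptote_k = asym * 2 * x$config$set_size,
    plateau_trial = if (is.null(x$plateaus)) NA_real_ else x$plateaus$trial_time[1],
    first_crossing = as.numeric(x$first_crossing),
    late_slope_post = x$late_trends$slope[x$late_trends$series == "post"],
    late_slope_retro = x$late_trends$slope[x$late_trends$series == "retro"],
    late_slope_benefit = x$late_trends$slope[x$late_trends$series == "benefit"]
  )
}

#' Simulate-and-recover study
#'
#' Repeats simulate-then-analyze over seeded replicates, tabulating the
#' generating benefit asymptote against the recovered one, the preferred
#' growth model, the plateau trial, and the first Bayes-factor crossing.
#'
#' @param config A [sim_config()]; its seed field is ignored in favor of the
#'   per-replicate substreams derived from `seed`.
#' @param replicates Number of replicates (>= 1).
#' @param seed Integer master seed.
#' @param window,draws,warmup,bf_threshold,persistence,loo,set_size Analysis
#'   settings passed to [run_analysis()]; replicate studies default to 600
#'   posterior draws, which is ample for the posterior means the curve fits
#'   consume.
#' @return A tibble with one row per replicate (`replicate`, `seed`,
#'   `true_asymptote`, `recovered_asymptote`, `recovered_k`, `preferred`,
#'   `plateau_trial`, `first_crossing`, `ok`), with a summary tibble
#'   (bias, RMSE, preference rate, crossing rate) in the `"summary"`
#'   attribute, also returned by [glance()] via [recovery_summary()].
#' @export
run_recovery_study <- function(config = sim_config(), replicates = 20,
                               seed = 1, window = 200, draws = 600,
                               warmup = 200, bf_threshold = 3,
                               persistence = 50, loo = FALSE,
                               set_size = NULL) {
  stopifnot_scalar_int(replicates, "replicates")
  set_size <- set_size %||% config$set_size
  true_asym <- switch(config$benefit$shape,
    logistic = config$benefit$l1 - config$benefit$l0,
    NA_real_
  )
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    rep_seed <- substream_seed(seed, "recover", r)
    cfg <- config
    cfg$seed <- rep_seed
    res <- tryCatch({
      trials <- simulate_trials(cfg)
      rep <- run_analysis(trials, window = window, set_size = set_size,
                          draws = draws, warmup = warmup,
                          bf_threshold = bf_threshold,
                          persistence = persistence, loo = loo,
                          seed = rep_seed)
      g <- glance(rep)
      tibble::tibble(replicate = r, seed = rep_seed,
                     true_asymptote = true_asym,
                     recovered_asymptote = g$asymptote,
                     recovered_k = g$asymptote_k,
                     preferred = g$preferred,
                     plateau_trial = g$plateau_trial,
                     first_crossing = g$first_crossing,
                     ok = TRUE)
    }, error = function(e) {
      warn(sprintf("Replicate %d failed: %s", r, conditionMessage(e)))
      tibble::tibble(replicate = r, seed = rep_seed,
                     true_asymptote = true_asym,
                     recovered_asymptote = NA_real_, recovered_k = NA_real_,
                     preferred = NA_character_, plateau_trial = NA_real_,
                     first_crossing = NA_real_, ok = FALSE)
    })
    res
  })
  attr(rows, "summary") <- recovery_summary(rows)
  rows
}

#' Summary statistics of a recovery study
#'
#' @param rows Output of [run_recovery_study()].
#' @return One-row tibble: replicate counts, asymptote bias and RMSE,
#'   model-preference rates, and the rate of sustained Bayes-factor
#'   crossings.
#' @export
recovery_summary <- function(rows) {
  ok <- rows[rows$ok, ]
  tibble::tibble(
    n_replicates = nrow(rows),
    n_failed = sum(!rows$ok),
    mean_recovered_asymptote = mean(ok$recovered_asymptote, na.rm = TRUE),
    bias = mean(ok$recovered_asymptote - ok$true_asymptote, na.rm = TRUE),
    rmse = sqrt(mean((ok$recovered_asymptote - ok$true_asymptote)^2, na.rm = TRUE)),
    mean_recovered_k = mean(ok$recovered_k, na.rm = TRUE),
    pref_logistic = mean(ok$preferred == "logistic"),
    pref_linear = mean(ok$preferred == "linear"),
    pref_exponential = mean(ok$preferred == "exponential"),
    crossing_rate = mean(!is.na(ok$first_crossing)),
    median_crossing = stats::median(ok$first_crossing, na.rm = TRUE),
    median_plateau = stats::median(ok$plateau_trial, na.rm = TRUE)
  )
}
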