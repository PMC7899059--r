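# cuecurve

Learning-curve analysis for retro-cue change-detection experiments.

In a change-detection task, an observer memorizes an array of items and
judges whether a probed item changed. A **retro-cue** — a spatial cue shown
after the memory array disappears but before the probe — reliably improves
performance over a **post-cue** baseline, and the size of that benefit,
tracked over thousands of interleaved practice trials, discriminates two
accounts of visual working memory: if retro-cues retrieve items from a
separate high-capacity store, the benefit should keep growing with practice;
if they redistribute attention within a capacity-limited store, it should
rise and saturate at a modest level.

cuecurve turns trial-level binary outcomes (observer × session × condition ×
trial index × correct/incorrect) into that discrimination:

- **Smoothing** — an edge-shrinking centered moving average converts each
  observer's 0/1 sequence into a continuous accuracy trace; window width
  `W` averages `W + 1` trials in the interior and shrinks symmetrically at
  the ends.
- **Group model** — per trial time and condition, a hierarchical normal
  model (truncated-normal prior on the population mean, half-normal on the
  between-observer SD, Gibbs-sampled) yields the population accuracy, its
  uncertainty, and the between-observer spread.
- **Capacity** — accuracy maps to Cowan's k by
  `k = (2 * accuracy - 1) * set_size`, so a benefit of 1/12 accuracy at set
  size 12 is 2 items.
- **Model comparison** — linear `m·x + c`, exponential `a·e^(-k·x) + c` and
  logistic `l1 + (l0 - l1)/(1 + (x/x0)^k)` curves are fitted to the benefit
  trace by deterministic profiled least squares and ranked by
  `BIC = -2·LL + ln(N)·k`; leave-one-observer-out refits probe robustness.
- **Plateau** — the trial at which the fitted logistic's derivative drops
  below a rate threshold (default 0.01% accuracy per trial) for good.
- **Evidence** — per trial time, a pooled effect size
  `d = (mu1 - mu2)/sqrt((s1^2 + s2^2)/2)` and a one-sided default Bayes
  factor (standard Cauchy prior on the effect size, truncated to positive)
  from the paired per-observer differences, plus the first trial from which
  BF stays above a threshold.
- **Synthetic cohorts** — a generator with drifting baselines, a logistic
  (or linear/exponential) benefit, and observer random effects, for
  parameter-recovery and power studies.

## Worked example

```r
library(cuecurve)

trials <- simulate_trials(sim_config(n_observers = 10,
                                     trials_per_condition = 800, seed = 42))
report <- run_analysis(trials, window = 200, draws = 1000, warmup = 300,
                       seed = 42)
report
```

```
<cue_report>
  10 observers, trial times 1..800, window 200, seed 42 (v0.1.0)
  preferred growth model: logistic
    linear      BIC    -4307.3  (dBIC  317.6)
    exponential BIC    -4491.8  (dBIC  133.1)
    logistic    BIC    -4624.9  (dBIC    0.0)
  leave-one-out preferences: logistic=10
  plateau (|slope| < 0.0001/trial): trial 139
  plateau (|slope| < 1e-05/trial): trial 190
  logistic benefit asymptote: 0.0424 accuracy (= 1.02 items at set size 12)
  first sustained BF >= 3 crossing: 102
  late trend [500..800] post:    slope +6.37e-05 [+4.67e-05, +8.07e-05]
  late trend [500..800] retro:   slope +4.25e-05 [+2.82e-05, +5.68e-05]
  late trend [500..800] benefit: slope -2.12e-05 [-4.14e-05, -1.04e-06]
```

Reading this: the benefit is best described by a saturating logistic (lower
BIC than linear by 318 — the "keeps growing" account loses), and every
leave-one-observer-out permutation agrees. The benefit stops changing
meaningfully around trial 139 and the group-level Bayes factor for a
positive benefit stays above 3 from trial 102 on. Accuracy keeps creeping up
in *both* conditions late in practice (positive post and retro slopes) while
the benefit itself drifts slightly down — the signature of general task
learning on top of a saturated cue benefit. The fitted asymptote (0.042
accuracy ≈ 1 item here) sits below the generating value because the default
generator's condition drifts differ, pulling the late benefit down; see the
methods vignette (`vignettes/cuecurve-methods.Rmd`) for why, and
`run_recovery_study()` to calibrate this for any design.

`glance(report)` returns the same summary as a one-row tibble;
`write_report(report, dir)` emits `smoothed.csv`, `group.csv`,
`benefit.csv`, `models.csv`, `evidence.csv` and `summary.txt`.

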