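---
title: "How cuecurve models retro-cue learning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How cuecurve models retro-cue learning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

In a retro-cue change-detection experiment, an observer memorizes an array of
items (here, `set_size = 12` oriented bars) and later judges whether a probed
item changed. In the *retro-cue* condition a spatial cue presented after the
memory array but before the probe indicates which item will be tested; in the
*post-cue* baseline the cue arrives with the probe. The two conditions are
interleaved, so both can be treated as parallel trial sequences sharing a
common "trial time" axis: trial time 100 means the 100th post-cue trial or
the 100th retro-cue trial of that observer.

The quantity of interest is the **retro-cue benefit** — retro-cue accuracy
minus post-cue accuracy as a function of practice. If retro-cues give access
to a separate high-capacity memory store, the benefit should keep growing
with training toward the set size; if they merely redistribute attention
within capacity-limited visual working memory, the benefit should rise and
then saturate at a modest level. Discriminating "keeps growing" from
"saturates" is a model-comparison problem on a learning curve, and that is
what this package implements: smoothing, group-level estimation, growth-curve
fitting with BIC selection, plateau detection, and a per-trial evidence
trace.

Accuracy is translated into capacity via Cowan's k for single-probe change
detection,

$$k = (2 \cdot \mathrm{accuracy} - 1) \cdot \mathrm{set\ size},$$

a linear map under which a benefit of 1/12 in accuracy at set size 12 equals
2 items of capacity.

## Smoothing binary outcomes

`moving_average()` turns the 0/1 outcome sequence of one observer-condition
series into a continuous accuracy estimate. The value at trial $t$ is the
mean of outcomes in $[t - h(t),\; t + h(t)]$ with half-width
$h(t) = \min(W/2,\, t-1,\, N-t)$, where $W$ is the nominal window width
(default 200). In the interior the window is a centered, odd-length span of
$W + 1$ trials including the current trial; near either end it shrinks
symmetrically rather than extrapolating. We include the center trial because
a symmetric odd-length window makes the interior estimate unbiased at $t$;
alternative conventions (center-exclusive, one-sided) differ by $O(1/W)$ and
are isolated behind the single `window` argument should they ever need to be
swapped.

Values within $W/2$ trials of either end rest on fewer trials; they are
computed normally but flagged (`caution` in `smooth_trials()` output) and
drawn faintly in plots. The moving average is a low-pass filter: the window
width trades variance against temporal resolution, and any statistic read
off the smoothed series (plateau trials, crossing times) is a function of
that choice. There is no "correct" window; 200 trials is the package default
for headline analyses and results for other windows can be produced by
re-running the pipeline.

## The group model

At each trial time and condition, the per-observer smoothed accuracies
$y_i$ are modelled hierarchically:

$$y_i \sim \mathrm{Normal}(\mu, \sigma^2), \qquad
  \mu \sim \mathrm{Normal}(0.5, 0.5^2)\ \text{truncated to}\ [0,1], \qquad
  \sigma \sim \mathrm{Half\text{-}Normal}(0, 0.5^2).$$

The hyperpriors are weakly informative on the accuracy scale: the $\mu$
prior covers the whole admissible range with most mass near the middle, and
the half-normal easily accommodates any plausible between-observer spread.
Inference is by Gibbs sampling — an exact truncated-normal draw for $\mu$
and a random-walk Metropolis step on $\log\sigma$ — with 4000 draws after
1000 warm-up by default, deterministic given the seed. All trial-time cells
are updated in one vectorized pass, so a full 2 × 1600-cell run costs about
as much as a single chain. Estimation is independent per trial time: the
smoothing step already supplies all temporal structure, and pooling across
trial times would double-count it.

Posterior summaries per cell are `mu` (population mean), `sigma_between`
(between-observer SD) and `se_mu` (posterior SD of the population mean, the
ribbon in the trace plots). A floor of $10^{-5}$ on $\sigma$ guards the
degenerate case of bitwise-identical observer values, where the SD would
otherwise random-walk to zero and collapse the sampler.

Two numerical notes. First, the model is checked in the tests against the
conjugate closed form under a Jeffreys prior (scaled-$t$ posterior for
$\mu$); that closed form has infinite variance for fewer than four
observers, so the spread comparison is made on a ten-observer fixture.
Second, capacity conversion applies Cowan's relation to `mu` rather than per
draw — the map is linear, so the two are equivalent for posterior means.

The benefit trace is the elementwise difference of the retro and post group
means, with uncertainty propagated as
$\sqrt{se_\mathrm{retro}^2 + se_\mathrm{post}^2}$ (the two samplers are
independent, which the tests verify at the draw level).

## Growth models and selection

Three candidate curves are fitted to the benefit trace by least squares:

| model | equation | parameters |
|---|---|---|
| linear | $m x + c$ | 2 |
| exponential | $a e^{-k x} + c$ | 3 |
| logistic | $l_1 + (l_0 - l_1) / (1 + (x/x_0)^k)$ | 4 |

The logistic tends to $l_0$ as $x \to 0^+$ and to $l_1$ as $x \to \infty$,
with inflection at $x_0$. Fits are ranked by
$\mathrm{BIC} = -2\,LL + \ln(N)\,k$ with the Gaussian log-likelihood at the
maximum-likelihood residual variance, $LL = -\tfrac{N}{2}(\ln(2\pi\,
\mathrm{RSS}/N) + 1)$, and $k$ counting curve parameters only (2/3/4).
Whether the residual variance is counted as a parameter shifts every BIC by
the same constant and cancels in the differences that drive selection. The
minimum-BIC model is preferred.

The nonlinear fits exploit conditional linearity: given the exponential rate
(or the logistic $(x_0, k)$ pair), the remaining parameters solve a linear
least-squares problem, so only a one- or two-dimensional profile is searched
— a log-spaced grid refined by golden-section search for the exponential,
and L-BFGS-B from a fixed 29-point multistart grid (x0 quantiles crossed
with exponents 0.5–6, plus a data-driven half-rise start) for the logistic.
No randomness enters, so repeated fits are bit-identical; ties are broken by
lowest RSS, then fewest iterations. Logistic asymptotes are bounded to
$[-0.5, 0.5]$ accuracy units (pass scaled bounds for traces on the capacity
scale), $x_0 \in [1, N]$ and $k \in (0, 20]$. A constant trace returns a
flat logistic flagged `degenerate`.

Two caveats are inherited from the procedure the package reimplements and
deliberately not "fixed". The residuals of a smoothed trace are strongly
autocorrelated (roughly $N/W$ effectively independent points rather than
$N$), yet the likelihood treats them as independent; BIC differences are
therefore sharper than the data warrant, and close calls — logistic versus
exponential in particular — flip more often across replicates than the BIC
margins suggest. And the trial times inside the smoothing caution margins
have strongly inflated variance but enter the unweighted least squares like
any other point. Both choices mirror the analysis convention of fitting the
full trace; the leave-one-observer-out report (`compare_models()` with
`smoothed`) is the built-in robustness check, re-running group estimation
and all fits with each observer removed.

`plateau_point()` locates where the fitted logistic stops changing
meaningfully: the smallest trial time at which the magnitude of the analytic
derivative falls below a rate threshold and stays below it, found by
bisection on the decreasing tail (search bounded at $10N$; default
thresholds $10^{-4}$ and $10^{-5}$ accuracy per trial, i.e. 0.01% and
0.001%). The derivative is invariant to vertical shifts, and halving the
threshold can only move the plateau later. `late_trend()` fits an ordinary
least-squares line (with its 95% CI) on a late window — by default trial 500
onward — to ask whether performance is still drifting upward after the
benefit has stabilized; its CI inherits the same autocorrelation caveat.

## Evidence trace

At each trial time the package computes the standardized effect size

$$d = \frac{\mu_1 - \mu_2}{\sqrt{(\sigma_1^2 + \sigma_2^2)/2}}$$

from the group-model summaries (equal SDs reduce it to classical Cohen's
d), and a directional default Bayes factor from the one-sample $t$ statistic
of the paired per-observer differences: effect sizes under the alternative
follow a standard Cauchy (Student's $t$, df = 1) truncated to positive
values, and the marginal likelihood is integrated by adaptive quadrature
(relative tolerance $10^{-6}$; a fixed-grid trapezoid rule serves as the
independent oracle in the tests). The within-subject pairing motivates the
one-sample form with $n$ = number of observers; a switch (`source =
"group"`) instead derives the statistic from the group-model effect size for
users who prefer posterior quantities throughout.

"Reliably crosses the evidence threshold" is operationalized by
`first_crossing()`: the smallest trial time from which the Bayes factor
stays at or above the threshold (default 3) for `persistence` consecutive
trials (default 50). The persistence rule replaces an eyeballed judgement
with a reproducible one; both knobs are exposed. Consecutive Bayes factors
are descriptive and deliberately not corrected for multiplicity.

## The synthetic cohort generator

`simulate_trials()` draws cohorts with the structure the analysis assumes,
for testing, parameter recovery and power exploration. Per observer and
trial $t$:

$$p_\mathrm{post}(t) = \mathrm{clip}\big(b + \beta_i + m_\mathrm{post}\,t\big),
\qquad
p_\mathrm{retro}(t) = \mathrm{clip}\big(b + \beta_i + m_\mathrm{retro}\,t +
\mathrm{benefit}_i(t)\big),$$

with outcomes drawn Bernoulli. Defaults: 10 observers, 1600 trials per
condition, baseline $b = 0.62$, drifts $m_\mathrm{post} = 6.2\times10^{-5}$
and $m_\mathrm{retro} = 3.7\times10^{-5}$ per trial (the late-phase slopes
such cohorts exhibit), and a logistic benefit with $l_0 = 0$, $l_1 = 0.083$
(2 items at set size 12), $x_0 = 150$, $k = 3$. Observer effects $\beta_i$
and perturbations of $l_1$ are Normal(0, 0.02); learning speed ($x_0$) can
optionally vary via `x0_sd`. Probabilities are clipped to $[0.05, 0.99]$ to
avoid degenerate Bernoulli streams while still permitting below-chance
stretches — chance level is deliberately not a floor, because smoothing and
estimation must tolerate below-chance data. Alternative benefit shapes
(`linear`, `exponential`) support misspecification scenarios; the
linear-truth scenario used in the tests sets the slope so the net benefit
grows by about 0.083 over the run.

One consequence of composing the defaults deserves emphasis: because the two
drifts differ, the generating benefit *declines* at
$2.5\times10^{-5}$ per trial after its logistic rise — from 0.083 near the
plateau to about 0.043 by trial 1600. A logistic fitted to such a trace
compromises between the rise and the decline, so the best achievable
noiseless asymptote estimate is about 0.056, not the generating $l_1$; noisy
replicates scatter widely around it. The recovery tests measure exactly
this behaviour. Users who want an unbiased recovery target should set the
drifts equal.

The generator also emulates the interleaving design (blocks of four trials
per condition in random order, exposed as a `presentation_index` column) and
an eight-session split, as metadata; the analysis consumes per-condition
trial times only. It does not simulate session-boundary discontinuities,
reaction times, stimulus properties, or gaze-contingent trial abortion —
real learning curves may show session-boundary structure the continuous
generator cannot, so passing recovery tests here does not certify behaviour
on such features.

## Seeds and determinism

A single integer seed is expanded into per-stage, per-unit substreams by a
fixed affine counter scheme (`stage` and `unit` codes hashed into a 31-bit
seed), so simulating three observers and then six reproduces the first three
exactly, and the group model, fits and evidence stages never share a stream.
The whole pipeline is byte-reproducible from (input, configuration, seed),
which the tests assert on written CSV output.

## Problem sizes used in the test suite

Unit tests run on small cohorts (3–8 observers, 40–400 trials, a few hundred
posterior draws), which exercise every code path in seconds. The acceptance
checks use the full default cohort design (10 × 1600 × 2) over 20 seeded
replicates per scenario with 600 posterior draws per group-model pass —
posterior means for curve fitting stabilize well below that, and the
replicate studies are the package's own calibration of what the design can
and cannot recover: generative-parameter arithmetic and noiseless fits are
recovered essentially exactly, while logistic-versus-exponential preference
on noisy default cohorts is genuinely marginal (the autocorrelation caveat
above), and the suite reports the measured rates rather than idealized
ones.

## Known limitations

- BIC treats smoothed points as independent; model preference probabilities
  are overstated by the BIC margins. Use the leave-one-out report.
- Edge trial times (within half a window of either end) carry inflated
  variance into unweighted fits.
- The Bayes factor trace is descriptive: no sequential error control.
- The group model is Normal on the accuracy scale; a beta-binomial
  likelihood would respect the unit interval more faithfully and is a noted
  extension.
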