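---
title: "Models and design choices in shakebox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in shakebox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shakebox)
```

## The discriminability model

shakebox scores a numerosity contrast — two candidate counts of marbles, one
of which is actually hidden in a shaken box — with an equal-variance
signal-detection model on a log numerosity scale. Each count $n$ is
represented internally as a Gaussian with mean $\log n$ and standard
deviation $\sigma$, so the contrast between $l$ and $m$ has

$$d' = \frac{|\log l - \log m|}{\sigma}.$$

Two consequences matter for everything downstream. First, $d'$ depends only
on the ratio of the counts (Weber's law): 8-vs-2 and 4-vs-1 are equally
discriminable. Second, the hidden alternative is irrelevant — the score is a
property of the pair. `sigma` defaults to 1, so $d'$ is reported in
natural-log units; any other log base would be absorbed into $\sigma$, which
is why the base is fixed. Only *relative* discriminability matters for the
regression analyses, so rescaling $\sigma$ rescales slopes without changing
conclusions.

An equal-variance ideal observer deciding which of the two alternatives
generated a percept is correct with probability $\Phi(d'/\sqrt 2)$
(`accuracy_2afc()`): chance at $d' = 0$, approaching 1 for easy contrasts.

Two heuristic difficulty models are registered alongside: the absolute
difference $|l - m|$ and the negative ratio $-\min/\max$. The negative-ratio
convention was chosen so that the identical pair scores $-1$ (hardest) and
scores increase toward 0 as the ratio departs from 1; with this orientation
all three models agree that an identical pair is the hardest possible case,
and the ratio heuristic induces *exactly* the contrast ordering of $d'$
(both are monotone in $\max/\min$), while the absolute difference does not
(it calls 9-vs-5 easier than 2-vs-1; $d'$ says the opposite). Internally
$d'$ is computed as $\log(\max/\min)$ rather than $|\log l - \log m|$ —
algebraically identical, but exact in floating point for equal-ratio pairs,
so the two orderings agree bit-for-bit.

## Playtime normalization and the regression battery

Children differ enormously in how long they play overall, so raw seconds are
converted to a per-child share: each trial's playtime divided by the child's
total across their trials, times the number of trials
(`normalize_playtimes()`). The per-child mean is exactly 1; a value of 1.3
means 30% more than an even share. Multiplying one child's raw playtimes by
any constant leaves their normalized values unchanged, which is the point.

The headline regression (`fit_playtime_regression()`) is trial-level OLS of
normalized playtime on $-d'$, with cluster-robust (CR1) standard errors by
child and a $t_{G-1}$ critical value ($G$ = number of children). The
estimator choice was genuinely open: because normalization already removes
per-child intercepts, OLS with clustering is the minimal faithful choice,
and a per-child random-intercept mixed model (`estimator = "mixed"`, via
lme4) is provided as an option — on balanced data the two agree closely,
and the mixed model's child-intercept variance is typically estimated at or
near zero for normalized outcomes (a boundary fit, reported as such by
lme4), which is expected rather than alarming. The predictor enters
unstandardized in natural-log units, so with counts 1–9 ($d'$ span about
2.1) a slope of 0.24 means the hardest contrast earns roughly half an even
share more playtime than the easiest.

Companion regressions use the same machinery: `hidden_count` (the count
actually in the box — null by design), `trial_order` (coded 1–4), and `age`
(years). One consequence of full normalization is worth knowing: any purely
between-child predictor, age included, has an *exactly* zero OLS slope
against normalized playtime, because every child's outcome mean is pinned
to 1. The age row is therefore a structural null here; an age analysis with
content would need a per-child summary outcome (e.g. the hardest-minus-
easiest playtime difference) rather than trial-level normalized playtime.

Accuracy is analyzed by logistic regression of correctness on $d'$ with the
same child clustering (`fit_accuracy_regression()`). Perfect separation —
e.g. an all-correct table — is reported as a flagged, non-converged row
rather than an error, since small samples of easy contrasts produce it
routinely.

Condition-level agreement with the model is summarized by the Pearson
correlation between per-contrast mean normalized playtime and $-d'$
(`condition_mean_correlation()`), and individual-level agreement by the
per-child OLS slope of normalized playtime on $-d'$
(`individual_slopes()`): a positive slope means that child explored longer
on harder contrasts. The proportion of positive slopes gets a binomial CI,
with both the normal approximation and the exact Clopper–Pearson method
selectable — published analyses of this kind have used both conventions, so
the method is always recorded in the output.

## Forced-choice proportions

For designs where each child makes one binary choice of the more
discriminable box, `proportion_with_ci()` implements the Bernoulli
normal-approximation interval $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/n}$,
clipped to $[0,1]$ and flagged when clipped or degenerate, plus the exact
Clopper–Pearson interval. The multiplier is fixed at 1.96 rather than a
re-derived quantile so printed intervals are bit-reproducible. The companion
`binomial_test_vs_chance()` uses the "minlike" two-sided convention (sum of
all outcome probabilities no larger than the observed one), the convention
of `stats::binom.test`. Display rounding uses round-half-up
(`round_half_up()`), matching how such intervals are conventionally printed.

## What the synthetic generator emulates — and what it does not

`generate_exploration_trials()` exists so every stage of the pipeline can be
exercised, and its estimators validated by parameter recovery, without any
behavioral data. It emulates the *statistical structure* the analyses
assume:

- per-child multiplicative baselines (log-normal, SD `child_sd` = 0.5,
  median raw playtime `base_playtime_s` = 10 s);
- expected normalized playtime
  $1 + \theta(x_c - \bar x_{child}) + \beta_{order}(j - 2.5) +
  \beta_{content}(h - \bar h_{child})$ with $x = -d'$, defaults
  $\theta = 0.24$, $\beta_{order} = -0.051$, $\beta_{content} = 0$;
- additive Gaussian trial noise on the normalized scale
  (`noise_sd` = 0.15), with a 0.05 positivity floor; a log-normal noise
  variant (`playtime_scale = "log"`) is exposed because exploration-time
  analyses are commonly robust across both scales and no noise model is
  canonical;
- correctness Bernoulli with $\mathrm{logit}(p) = \beta_0 + \beta_1 d'$,
  defaults $\beta_0 = 0$ (chance at zero discriminability, the
  forced-choice floor) and $\beta_1 = 1.12$;
- counterbalancing by a balanced 4×4 Latin square for trial order and
  alternating-block flips of which alternative is hidden, giving exact
  balance whenever the number of children per experiment is a multiple
  of 4 (default 24).

The slope, trial-order, and accuracy defaults are the package's calibrated
reference values: recovery tests and the acceptance script check that the
pipeline retrieves them from data generated under them.

Default problem sizes were chosen to keep the full test suite and
acceptance runs fast while leaving estimator standard errors well inside
the ranges of interest: 24 children per experiment (96 total, 384 trials)
for the exploration analyses, 5000 children for the logistic recovery
check, and 200 generator seeds for the CI-calibration properties.

What it does *not* emulate: acoustic or motor realism (no marble sounds, no
accelerometer stream), dropout or experimenter error, heavy-tailed or
skewed playtime noise, age effects (ages are simulated but have no
generative role), and any within-child learning beyond the linear trial
trend. Passing recovery tests therefore show that the *estimators* are
correct and calibrated for data with this covariance structure — not that
real children behave like the generator.

### The default contrast sets

The main text of typical reports pins down only the numerosity range (1–9)
and a few anchor contrasts, so the default sets are a documented,
configurable placeholder chosen by three design rules:

1. **Span**: overall $d'$ runs from 0.13 (8 vs 7) to 2.2 (9 vs 1), with
   each experiment containing hard, medium and easy contrasts.
2. **Equal set means**: the product of count ratios is exactly 48 in every
   set, so each experiment's mean $d'$ is identically $\log(48)/4$. The
   generator centers $-d'$ within child (equivalently, within experiment),
   so the pooled trial-level slope estimand equals
   $\theta \cdot V_w/(V_w + V_b)$, where $V_b$ is the between-experiment
   variance of set-mean $-d'$; equal means make $V_b = 0$ and the estimand
   exactly $\theta$, and also make noiseless generation exactly linear in
   $-d'$ across the whole design (condition-mean $r = 1$).
3. **Content balance**: across the 16 contrasts, the expected hidden count
   under counterbalancing is numerically decorrelated from $d'$, so the
   content regression is null *by design*. Without this constraint, hard
   contrasts (adjacent large counts) would systematically contain more
   marbles than easy ones and a marginal content regression would inherit
   a spurious slope from the discriminability effect.

The third set reproduces a fixed-content design: its hidden count is pinned
to 8 or 3 for every child, each content level appearing with one hard and
one easy contrast, dissociating content from contrast within one
experiment.

## Numerical and degenerate-input choices

- Ranking ties (`rank_contrasts()`) break by smaller maximum count, then
  smaller minimum count, so output ordering is deterministic.
- Children with zero total playtime cannot be normalized and are excluded
  with a warning; negative playtimes are a data error.
- Children whose trials share one $d'$ value have no defined individual
  slope and are excluded with a warning.
- A constant predictor raises a degenerate-design error; a single child
  makes clustered standard errors meaningless and is an error.
- Normal-approximation CIs at $\hat p \in \{0, 1\}$ are zero-width and
  flagged; clipping at the $[0,1]$ boundary is flagged.
- AIC comparisons in `compare_models()` are computed on identical
  observation sets for every model, from the Gaussian likelihood on the
  normalized scale (matching the OLS estimator).
- All model easiness scores are negated before regression so that every
  fitted slope is positive-signed and comparable across models.

## Reproducibility

A `(config, seed)` pair fully determines every generated table and
therefore every downstream CSV; the pipeline stages write JSON manifests
recording the config snapshot, seed, package version and output files.
CSVs are UTF-8, comma-separated, header row mandatory, `.` decimal
separator.

## Known limitations

- The generator's Gaussian noise on the normalized scale is a convenience;
  real playtime distributions are right-skewed. The log-scale option
  mitigates but does not model this.
- `sigma` is a single free parameter; unequal-variance or empirically
  estimated discriminability functions are not implemented, though the
  model registry (`difficulty_score()`) is the extension point.
- The clustered-OLS CIs are asymptotic in the number of children; with very
  few children the mixed-model option (or an exact method) is preferable.
- Forced-choice analyses treat each child as one Bernoulli trial; no
  covariates are modeled for choices.
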