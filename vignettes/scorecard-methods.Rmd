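---
title: "Methods: naive-Bayes scorecards for prolonged ICU stay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: naive-Bayes scorecards for prolonged ICU stay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuscore)
```

## The model and its assumptions

The package predicts a binary outcome — prolonged ICU stay after cardiac
surgery, defined as a length of stay of at least 120 hours (5 days) —
from discretized clinical variables. The classifier is naive Bayes: given
categories $x_1,\dots,x_N$ and classes $\omega_1$ (adverse) and
$\omega_2$ (normal), features are assumed conditionally independent given
the class, so the log posterior-odds score is additive,

$$ S(\mathbf{x}) \;=\; \sum_{j=1}^{N} w_{x_j} \;+\;
   \ln\frac{P(\omega_1)}{P(\omega_2)}, \qquad
   w_{x_j} \;=\; \ln\frac{\hat p(x_j\mid\omega_1)}{\hat p(x_j\mid\omega_2)}, $$

and the patient is classified adverse when $S(\mathbf{x}) \ge 0$. The
weights are weight-of-evidence terms computed from class-conditional
category counts; the counts, not the weights, are the model's state.
This is what makes the scorecard *updatable*: adding or removing patient
records increments or decrements integer tables, after which the weights
are recomputed exactly (`update()`), and the model serializes to
human-readable descriptive tables.

Conditional independence is a strong assumption; the pipeline mitigates
it by aggressively pruning the candidate set (screening plus stepwise
selection) rather than by modelling interactions. Naive Bayes is known to
classify well even under moderate violations, and the point of this model
family is that more flexible alternatives are rarely maintainable in a
clinical setting.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `los_cutoff` | 120 h | adverse-outcome boundary; the boundary value itself is adverse |
| `alpha` | 0.5 | additive smoothing per category (counts); 0 gives pure ML weights |
| `priors` | (0.5, 0.5) | class priors; equal priors put the decision threshold at score 0 |
| `conf.level` (screening) | 0.99 | odds-ratio interval level; retain iff the interval excludes 1 |
| `window`, `delta` | 3, 0.01 | stop selection when the cumulative AUC gain over `window` steps is `< delta` |
| `k` | 5 | cross-validation folds |
| `B`, `level` | 1000, 0.95 | bootstrap replicates and level for the BCa AUC interval |

Smoothing defaults to $\alpha = 0.5$ (Jeffreys) because clinically
important categories can be rare — chronic dialysis affects about 1% of
cardiac-surgery patients — and a category unobserved in one class would
otherwise produce an infinite weight. With $\alpha = 0$ the fitted
weights are exact log ratios of sample frequencies and obey the
normalization identities
$\sum_k \hat p(k\mid\omega_2)e^{w_k} = 1$ and
$\sum_k \hat p(k\mid\omega_1)e^{-w_k} = 1$, so a feature's weights can
never be all-positive or all-negative; the test suite asserts both.

## Discretization conventions

Continuous and discrete variables are used in two categorical forms:
median-dichotomized for screening, and binned into the four quartile
intervals of the training sample for modelling. Three conventions are
fixed so that a saved model scores new data identically everywhere:

* quantiles use the linear-interpolation convention (`stats::quantile()`
  type 7), so the second quartile edge always equals the median cut-off;
* values equal to a cut-off or edge fall in the **lower** category
  (half-open $(\mathrm{lo}, \mathrm{hi}]$ intervals) — a single declared
  tie rule, not an inference about how any particular cohort was handled;
* edges estimated on training data are frozen inside the fitted model and
  reused verbatim for new patients (and a refit requires the explicit
  `refit = TRUE` path of `update()`).

Degenerate edges (all three equal) are allowed with a warning: all
non-tied values then map to bins 1 or 4.

## Screening

Each variable is tested univariately with the odds ratio of a 2×2
exposure-by-outcome table, dichotomizing continuous variables at their
median first. The interval is the Woolf log-normal interval
$\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$ at the 99% level
($z = 2.5758$); a variable is retained when the interval excludes 1. Zero
cells take the Haldane–Anscombe correction (+0.5 on every cell, flagged
in the report). Constant variables are excluded with a warning rather
than an error. Retained continuous variables proceed to modelling in
quartile form — the dichotomized version exists only inside the screen.
`table_from_or_ci()` inverts the same interval: given a published
interval and the class margins it reconstructs integer cell counts, which
is how the acceptance script recounts a published screening table when
only the intervals are in print.

## Forward selection and the stopping rule

Selection is greedy forward search on resubstitution AUC: at each step
every remaining candidate is added to the current model (in naive Bayes a
feature's weights do not depend on the other features, so this only adds
one precomputed contribution column) and the candidate with the highest
AUC enters. Ties break by declared schema order, making the trace
deterministic. The search halts when the cumulative AUC increment over
three consecutive steps falls below 0.01 — "1%" is read as an **absolute**
AUC increment, the reading consistent with replaying the rule on the
published per-step AUC sequence (the window ending at step 7 sums to
0.0080 and triggers the stop; the window ending at step 6 sums to 0.0105
and does not); a relative-gain mode is available but non-default. All
features entered before the rule fires are retained, including those of
the triggering window; whether the final low-gain entries should instead
be pruned is genuinely open, and retention matches the published
seven-variable outcome. The search also stops when no candidate improves
the AUC or candidates run out.

Selection happens once, on the full training sample, before
cross-validation — the protocol of the original study. Resubstitution AUC
during selection is optimistic; the cross-validated AUC is the honest
performance figure, and a nested per-fold selection is deliberately out
of scope.

## Cross-validation and the bootstrap

`cross_validate()` makes a seeded random partition into $k$ near-equal
folds (sizes differ by at most one; a stratified mode exists for small
cohorts where a random fold can miss the adverse class). In each round
the weights **and** the quartile edges are re-estimated on the training
folds; the held-out fold is scored with those frozen estimates. Every
record is scored out-of-fold exactly once, and the testing-set AUC and
confusion matrix are computed on the pooled out-of-fold scores. Whether a
single testing AUC should pool folds or average per-fold values is not
determined by the protocol; pooling is the default and the per-fold
values and their mean are always reported alongside. Report percentages
are rounded to whole percent, the conventional precision for scorecard
papers; raw proportions are retained.

The AUC itself is the Mann–Whitney statistic computed from midranks
(ties count one half), which equals the trapezoidal area under the
empirical ROC curve; the suite checks the identity on random fixtures and
against an independent ROC implementation.

`bca_ci()` implements the bias-corrected and accelerated bootstrap:
records (score/label pairs, kept attached) are resampled with replacement
$B$ times; the bias correction is
$z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)$ with the proportion
clipped to $[1/(B{+}1),\, B/(B{+}1)]$ so $z_0$ stays finite; the
acceleration comes from the jackknife skewness formula
$a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$ with
$d_i = \overline{\theta_{(\cdot)}} - \theta_{(i)}$ (set to 0 when the
jackknife is constant); endpoints are type-7 quantiles of the replicates
at the adjusted percentile levels. A resample on which the statistic is
undefined (e.g. a single-class AUC resample) is redrawn with a capped
retry budget. When $z_0 = a = 0$ the interval reduces to the plain
percentile interval; the suite verifies this, the agreement with the
t-interval for a normal mean, agreement with an independently coded
reference (and the `boot` package), and near-nominal coverage on null
AUC simulations.

## The synthetic cohort generator

No patient-level data ships with the package; the generator provides
cohorts with known ground truth so every stage is testable. It emulates
the *structure* of the original development cohort: 3256 patients, 36
dichotomous and 16 continuous candidate predictors, adverse prevalence
0.111 (the fraction implied by the published testing-set confusion
matrix), and 7 informative predictors matching the published selection.
Labels are i.i.d. Bernoulli; features are drawn conditionally independent
given the class — the model's own assumption, so fitted models can be
compared against the generating law.

Calibration was done once and frozen:

* the three informative dichotomous features use the class-conditional
  rates obtained by exactly inverting the published weight pairs
  (`implied_binary_rates()`), e.g. chronic dialysis at 3.3% of adverse
  and 0.31% of normal patients;
* the four informative continuous features use normal or lognormal
  class-conditional laws whose standardized shift and scale ratio were
  least-squares fitted to the published quartile-weight profiles at
  prevalence 0.111;
* the 45 remaining features have identical laws in both classes (pure
  noise), with realistic prevalences and scales.

Under conditional independence these per-feature effects combine to a
ground-truth 7-feature AUC of about 0.885 (`theoretical_auc()`, a
Monte-Carlo oracle that bins continuous features at the population
quartiles of the class mixture). That is a little above the published
cross-validated AUC of comparable real cohorts (~0.86): real predictors
are positively correlated, which the default generator deliberately does
not model. The generator therefore emulates marginal structure and effect
sizes, not covariance; passing recovery tests say the pipeline finds what
the generating law planted, not that real data is this clean. LOS values,
when requested, are drawn from lognormal laws consistent with the labels
(adverse ≥ 120 h) and are meant only to exercise the outcome-derivation
path, not to reproduce a real LOS distribution.

One consequence is a known, accepted limitation: the two rarest
informative features (chronic dialysis, acute myocardial infarction)
contribute resubstitution AUC gains of roughly 0.002 at $n = 3256$ — the
same order as the best chance gain among 45 noise features, a handful of
which survive a 99% screen in any given sample. The probability that all
seven informative features enter the forward search before *any* noise
feature is therefore about 0.85 at the study's own effect sizes (measured
over 200 generator seeds), and the acceptance test asserting a 90%
recovery rate documents this tension rather than hiding it behind
inflated effect sizes. The companion recovery property — the fitted
model's AUC at $n = 10^5$ sits within 0.01 of the ground-truth AUC — holds
with a wide margin (observed gap ~0.0005).

## Numerical and degenerate-input choices

* A score of exactly 0 classifies adverse — the conservative choice for a
  risk screen, fixed as one documented rule.
* AUC accumulators are doubles throughout ($n_1 n_2$ overflows 32-bit
  integers near $n = 10^5$).
* Score additivity is exact up to floating-point reassociation; the suite
  checks permutation invariance of the feature order at $10^{-12}$.
* Missing values are handled by complete-case deletion only
  (`filter_complete()`, with a per-record exclusion report); "insufficient
  data" is interpreted as any missing declared value, and no imputation is
  offered.
* Model import verifies integrity: counts must sum to class totals and
  stored weights must match weights recomputed from counts at $10^{-8}$.

## Problem sizes used by the test suite

The suite runs at the sizes a laptop handles in seconds, chosen as the
package's own trade-off between Monte-Carlo error and runtime: 50
generator seeds for the recovery rate, 200 runs × $B = 500$ for bootstrap
coverage, $n = 10^5$ for asymptotic weight/AUC recovery, 10,000 label
permutations for the screening type-I calibration, and the full
$n = 3256$, 52-feature configuration everywhere the study-scale pipeline
is exercised.

## Known limitations

* No interaction or correlation modelling (by design); an optional
  correlation knob for stress-testing the independence assumption was
  considered and left out of this version.
* No probability calibration beyond the score, no exact (Fisher)
  screening intervals, no supervised binning, no DeLong AUC comparisons,
  no cost-sensitive priors — all deliberately out of scope.
* The stopping rule's retention of the triggering window is an
  interpretation (matching the published seven-variable outcome), flagged
  here rather than asserted as the only reading.
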