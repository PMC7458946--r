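---
title: "Modeling clinical-trial quality risk from audit findings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clinical-trial quality risk from audit findings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifrisk)
```

## The problem

Sponsor audit programs visit only a fraction of investigator sites, and
audits report issues that have already happened. A risk model that scores
prospective (study, site) combinations lets quality professionals direct
attention before issues occur. The unit of analysis is a single audit or
inspection activity; the outcome, per Clinical Impact Factor (CIF), is
whether the activity produced **at least one** finding of that CIF. Five
binary classification problems result — consent, safety, data integrity,
protecting primary endpoints, sponsor oversight.

Two properties of such data dominate every design choice here. First, the
base rates are high (55–86% of activities have at least one finding of most
CIFs), so the interesting output is a *calibrated probability*, not a
classification. Second, the signal-to-noise ratio is low: automated feature
selection (trees, forests, lasso) fits noise, so the model family is a plain
logistic regression over a small set of hand-crafted binary features, with
an information-criterion search as the only automated step.

## The model

For CIF $c$ and activity with binary feature vector $x$:

$$ P(\text{finding}_c = 1 \mid x) = \sigma\!\left(\beta_{0c} + \sum_j \beta_{jc} x_j\right), \qquad \sigma(z) = \frac{1}{1+e^{-z}}. $$

Coefficients are maximum-likelihood estimates (IRLS via `stats::glm`),
unpenalized, with explicit convergence (score norm) and perfect-separation
checks. Risk is additive on the log-odds scale; for most activities only one
or two features fire, so higher-order additivity is essentially untestable
at this scale — one known interaction (randomization × design) is instead
materialized as two mutually exclusive features, `nonrand_parallel_or_sequential`
and `nonrand_single_group`.

## Feature engineering

All model inputs are 0/1 (`build_feature_matrix()`):

* **Continuous site measures** are Yeo-Johnson transformed
  (`yeo_johnson_transform()`, $\lambda$ by maximum likelihood over
  $[-3, 3]$ via golden-section search, then standardized), quantile-binned
  into 5 segments (`bin_into_segments()`), and binarized against selected
  segments. Because Yeo-Johnson is monotone, segment membership equals
  direct rank thresholding of the raw values — a property the tests verify —
  so the transform matters for inspection of the EDA scale, not for the
  binary features themselves.
* **Categorical levels** below 5% prevalence are pooled into `other`
  (`group_rare_levels()`) before binarization, so no near-zero-variance
  indicator reaches the models; missing values are treated as "no" (0).
* **Site burden score** (`site_burden_score()`): within a study, sites are
  ranked (average ranks for ties) by the number of concurrent sponsor
  trials in the same therapeutic area; the rank divided by the number of
  sites gives a score in (0, 1]. Average ranks make the score independent of
  input order; the banded indicator used as a feature thresholds this score.
* Operational thresholds mirror the risk factors the field reports:
  fewer than 5 / more than 32 patients enrolled, screen-failure rate above
  0.62, AE reporting within 2 days, 3+ parallel trials.

Any engineered feature whose realized prevalence falls below 5% is dropped
with a warning. The strongest absolute pairwise Pearson correlation is
reported (`max_abs_pairwise_correlation()`), and pairs with $|r| > 0.3$ are
barred from being co-selected — a conservative bound chosen above the
largest correlation reported for the real data (−0.21), since no explicit
rejection threshold is stated there.

## Feature selection

`select_features_bic()` runs a greedy forward search from the null model,
adding at each step the candidate that lowers
$\mathrm{BIC} = k\ln n - 2\ell$ the most and stopping when no candidate
lowers it. The search is deterministic: candidates are scanned
alphabetically and ties break to the first name. Greedy search was chosen
over exhaustive enumeration for testability and speed; on candidate sets of
the size used here (≤ 15) the tests verify it reaches the exhaustive
$2^k$ minimum in ≥ 95% of simulated datasets. Selection uses only the first
five calendar years (2011–2015 under defaults) to keep the later years
untouched for honest backtesting; the final coefficients are then refit on
the whole span (`refit_on_all_data()`).

## Validation

`time_series_splits()` builds one split per year from the second onward:
train on all strictly earlier years, test on the year, *excluding* test
activities belonging to any study audited in an earlier year. The exclusion
prevents study-level information leaking from training to test; same-year
repeats are not excluded (the rule's source is silent on them, and excluding
them would shrink already small test sets). Exclusion applies to test sets
only. `backtest()` refits the fixed selected feature set per split — never
re-selecting — and reports AUC (rank/Mann-Whitney estimator with tie
correction) and Brier score as mean ± SE over splits (sample SD, $n-1$,
divided by $\sqrt{\text{splits}}$). A selected feature constant in one
split's training window is dropped from that split's refit (its coefficient
is unidentifiable there); a split with a single-class training outcome is
skipped; a single-class test year leaves AUC undefined (NA) while Brier is
still computed.

## Calibration

`bin_predictions()` divides the pooled cross-validated predictions' range
into 4 equal-width bins (half-open, last closed; empty bins retained).
`ci75()` computes the 75% **Wilson score interval** of each bin's observed
event proportion — Wilson rather than Wald because bins can be small and
proportions extreme, where the Wald interval degenerates. The step curve
(`fit_step_calibration()`) then applies three rules per bin:

1. **keep** — CI75 excludes the base rate: the step takes the bin's observed
   probability;
2. **merge** — CI75 overlaps the base rate and an adjacent bin also
   overlaps: the two pool (choosing the neighbor with the closer observed
   probability; ties to the larger-n neighbor, then left), in the hope the
   combined counts resolve the deviation;
3. **default** — an overlapping bin with no overlapping neighbor takes the
   base rate itself.

Merging only like-with-like keeps a confident neighboring bin from being
diluted by a weak one; empty bins are first absorbed into the nearest
non-empty neighbor via adjacent merges so the step ranges always partition
the binned span. At application time (`apply_calibration()`) predictions
clamp to the fitted range — the curve's purpose is to bound the model
output — and interior edges belong to the right-hand step. The width Δ of
the calibrated range is the headline per-CIF summary: Δ = 0 means the model
cannot move an activity's risk estimate away from the base rate.

A CIF whose selected model is the null model receives the constant
base-rate curve directly. An intercept-only model predicts a single number
per year; the small spread of its pooled cross-validated predictions is
refit noise, and binning that sliver would manufacture spurious
"deviations" at the 75% confidence level roughly a quarter of the time per
bin.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions of the dataset the
method was developed on: 8 years (2011–2018) at Poisson(86.7) activities
per year, 13% inspections (a label with no risk effect — audits and
inspections are pooled), 5.9 findings per activity, and per-CIF presence
base rates of 55/84/86/59/76%. Choices the descriptive statistics do not
pin down were fixed once, at values a trialist would call realistic:

* **Covariates.** Study attributes are drawn with fixed level
  probabilities (oncology 50%, reflecting the portfolio bias reported for
  the source data; pediatric 12%; phase I 15%); design is drawn conditional
  on randomization (non-randomized studies are mostly single-group), which
  also keeps both interaction features above the 5% rule. Site measures use
  negative-binomial enrollment (size 2, mean 20), Beta(2, 3) screen-failure
  rate, log-normal screening duration and AE latency, Poisson(2) parallel
  trials — supports chosen so the operational thresholds (5, 32, 0.62) fall
  strictly inside them.
* **Risk structure.** Per CIF, presence is Bernoulli with log-odds
  `intercept + x·beta` over ground-truth features; default betas
  (±0.4–0.8) mirror the directions reported for the real models. The
  intercept is solved by root-finding so the *realized* marginal presence
  rate equals the configured base rate — against the generated feature rows,
  which is exact whatever the covariate dependence; the standalone
  `intercept_for_base_rate()` implements the independent-Bernoulli
  enumeration form.
* **Finding multiplicity.** The models use only presence, but the
  descriptive statistics include a mean findings count, so counts are
  `presence × (1 + Poisson(mu))` with a single `mu` scaled to make the
  expected total findings per activity equal 5.9. A configuration whose
  mean findings target is below the sum of base rates is rejected as
  infeasible (each positive CIF contributes at least one finding).
* **Study persistence.** Studies stay auditable for 1 + Geometric(0.4)
  years, so repeat audits across years occur and the cross-validation
  exclusion rule does real work.

What the generator does **not** emulate: auditor selection bias (site
sampling is uniform within active studies), temporal drift in audit
strategy, correlated findings across CIFs beyond shared covariates, and
free-text finding statements (counts are generated directly). Passing tests
therefore demonstrate the pipeline's correctness and its behavior under a
known risk structure — not that real audit data carry recoverable signal.

## Numerical choices and degenerate inputs

* Logistic fits: IRLS with deviance tolerance 1e-12, score-norm check at
  1e-8·n, separation reported with the offending feature named.
* Yeo-Johnson: profile log-likelihood with the Jacobian term, optimized by
  `stats::optimize` (golden section) over [−3, 3]; constant input errors.
* Quantile binning: type-7 quantile boundaries, inclusive lower / exclusive
  upper, final segment closed; fewer distinct boundaries than segments
  collapse with a warning; all-equal input yields a single segment.
* All-identical predictions at calibration time give a single degenerate
  bin with a warning.
* BIC selection with an empty candidate set returns the null model with a
  warning; feature/correlation ties break deterministically
  (alphabetical / larger n / left).

## Problem sizes

Defaults were chosen to match the study conditions (~700 activities over
8 years). Unit and property tests run reduced configurations (4–6 years,
60–100 studies) and simulation checks use 20–50 seeds at n = 700–2000,
which keeps the full suite around a minute while leaving Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* Mapping free-text finding statements to CIFs is out of scope; inputs are
  already CIF-labeled counts.
* No Poisson/count modeling of multiplicity; the binary reduction is
  deliberate, matching the business question.
* The calibration step function is coarse (4 bins) by construction; small
  annual test sets do not support a smooth recalibration.
* With high base rates the models mostly resolve risk *decreases*; bins
  above the base rate rarely achieve CI75 exclusion at these sample sizes.
* The backtest's mean ± SE over 7 splits is a crude uncertainty summary;
  no bootstrap is attempted.
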