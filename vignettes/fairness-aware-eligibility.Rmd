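---
title: "Methods: fairness-aware screening eligibility on imbalanced cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fairness-aware screening eligibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the fairness
definitions it commits to, the model and threshold machinery, what the
synthetic-cohort generator does and does not emulate, the numerical
choices that matter, and the limits of what a passing test suite shows.

## Fairness definitions and the two working assumptions

Two group-level criteria are used, always over a binary race attribute
(black/white), optionally intersected with gender.

**Statistical parity difference (SPD)** is the difference in
positive-outcome probability between groups; 0 means the outcome is
independent of group membership. SPD is the quantity the pre-processing
stage drives to zero.

**Equal opportunity** compares true-positive rates: the equal opportunity
difference is

$$\mathrm{EOD} = \mathrm{TPR}_{\text{black}} - \mathrm{TPR}_{\text{white}},$$

so a positive EOD means white participants with the outcome are the
under-served group. The sign convention is configurable (`eod(order=)`);
this default makes the direction of disparity explicit rather than
reporting magnitudes only. EOD is never a single number here: it is a
series across cross-validation folds (training) or bootstrap replicates
(testing), summarized by its mean and tested against zero.

Using SPD-driven weights to pursue an equal-opportunity goal is coherent
only under two assumptions, which the generator makes true by default and
`base_rate_ztest()` can check on any cohort: (1) the true group base
rates are (statistically) equal, so parity is not at war with accuracy;
and (2) the sampled groups represent their populations, so observed rate
gaps are either noise or *injected* bias, not real epidemiology. When the
first assumption is violated — e.g. a genuine group-intercept difference
in the outcome model — parity reweighing overcorrects the TPR gap rather
than closing it. We observed exactly that during design, which is why the
generator's bias mechanisms are explicit and separable (below).

## Reweighing

For subgroups $s$ (levels of one attribute, or tuples over several) and
outcomes $y$, each cell gets

$$w(s, y) = \frac{\hat P(s)\,\hat P(y)}{\hat P(s, y)},$$

and every row inherits its cell's weight. Three consequences, all tested
as exact identities: the weighted (subgroup, outcome) joint factorizes
into its weighted marginals; the weighted SPD is zero (`<= 1e-12`) for
every attribute in the specification, including each marginal attribute
of an intersectional spec; and the mean row weight is 1, so weighted
likelihoods keep the scale of unweighted ones. An empty (s, y) cell is a
hard error naming the cell — Laplace-style smoothing would silently
change every other weight, and the caller can instead coarsen the
specification.

## The easy-ensemble classifier

At ~4% outcome prevalence, a single boosted model trained on the full
data concentrates on the majority class: at its native decision threshold
(0.5 on the margin scale) its minority-class recall is essentially zero
(a property test demonstrates this against the balanced ensemble).
Threshold post-processing can compensate for much of that — with a
per-model Youden threshold the single model's recall is comparable to the
ensemble's — but the balanced construction keeps the score scale
meaningful and the operating point stable, which the threshold stage then
exploits.

`fit_easy_ensemble()` draws `n_subsets` balanced under-samples (all
minority-class rows plus an equal-size uniform draw of majority rows,
without replacement; sub-ensemble $i$ is seeded with `seed + i`) and
boosts each with depth-limited `rpart` trees:

* weak learner: depth-1 stump by default (`weak_learner_depth`), fitted
  on the current instance weights;
* weighted error $\varepsilon$, stage coefficient
  $\alpha = \eta \log\left((1-\varepsilon)/\varepsilon\right)$ with
  learning rate $\eta$;
* misclassified rows' weights multiplied by $e^{\alpha}$, renormalized;
* early stop at $\varepsilon \ge 0.5$ (learner discarded), at an
  unsplittable node, or at $\varepsilon = 0$, where the perfect learner
  is kept with $\alpha$ capped at $\eta \log 10^{10}$ — a finite stand-in
  for the divergent coefficient.

The defaults (`n_subsets = 70`, `n_weak = 200`, `learning_rate = 0.1`)
are the tuned full-scale operating point of the framework; the test suite
and the acceptance script run a reduced 10 × 50 configuration, which
already recovers the generating model's discrimination to within 0.05
AUC on a 20,000-row cohort, and exercise the full 70 × 200 configuration
as a smoke test. Reweighing weights enter *only* as the boosting rounds'
initial instance weights; under-sampling stays uniform. The alternative —
weight-proportional sampling — would entangle the two mitigation stages
and is deliberately not done. Scores are the mean over sub-ensembles of
the normalized margin $\sum_m \alpha_m h_m(x) / \sum_m \alpha_m$ mapped
to $[0, 1]$; the mean is the conventional combiner and keeps the score an
average of bounded, comparable quantities.

The logistic arm (`fit_weighted_logistic()`) is a maximum
weighted-likelihood GLM with frequency semantics (duplicating a row ==
doubling its weight, tested). Under separation or non-convergence it
refits with a small ridge penalty (`1e-6` per observation on
non-intercept terms) via Newton-IRLS and records `ridged = TRUE`.

## Thresholds

The ROC is exact and empirical, over all distinct cut-points, with the
global convention *eligible iff score ≥ threshold*. `roc_auc()` is the
trapezoidal area, which equals the all-pairs concordance probability with
ties counted 1/2 — asserted as an exact identity on hundreds of random
instances, and the basis for the DeLong machinery below.

* `TY` (`youden_threshold()`): maximizes J = TPR − FPR; ties break toward
  the smaller threshold, i.e. toward sensitivity, the right tilt for a
  screening context.
* `TU` (`specificity_matched_threshold()`): the smallest cut-point whose
  specificity is **at least** the reference (the USPSTF rule's empirical
  specificity on the training data). "At least" rather than "nearest"
  semantics were chosen because the comparison this threshold exists for
  — more sensitivity at no specificity cost — needs the floor to be a
  guarantee, not an approximation. An unattainable reference returns the
  maximum cut-point flagged `attained = FALSE` instead of erroring, so a
  grid search can continue and audit the configuration.

During cross-validation TU/TY are re-derived on each fold's training
part (the leak-free reading of the training protocol; a construction
test perturbs held-out folds and asserts the fitted thresholds do not
move). For testing, the thresholds are frozen from the full training
split.

## Statistical protocol

* `eod_ttest()`: one-sample two-sided t on the EOD series, with a
  percentile 95% CI. Note the series is bootstrap replicates of *one*
  test split: the t-test treats them as independent, so its p-values are
  sharp by construction — this mirrors the published protocol and is why
  the effect sizes are reported alongside.
* `hedges_g_rm()`: repeated-measures standardized difference
  $d_{rm} = \bar d / s_d \cdot \sqrt{2(1-r)}$ times the small-sample
  correction $J = 1 - 3/(4(n-1)-1)$, $r$ the series correlation. When
  $x - y$ is exactly constant the formula is 0/0; the algebraic limit
  $\bar d / s_x$ is returned.
* `cl_effect_size()`: $\Phi(|\bar d| / s_d)$ on the paired differences;
  0.5 = no separation.
* `mcnemar_test()`: reports the continuity-corrected
  $\chi^2 = (|b-c|-1)^2/(b+c)$ always; the p-value uses the exact
  binomial when $b + c < 25$. Zero discordance is a flagged no-test.
* `delong_test()`: placement values $V^{10}, V^{01}$ per model, AUC as
  their mean, covariance of correlated AUCs from the placement
  components, two-sided z. Verified against a leave-one-out jackknife
  (within 10%) and an established independent implementation.
* `stratified_bootstrap_ci()`: resampling within outcome strata keeps
  every replicate evaluable at 4% prevalence; failed replicates are
  dropped and counted, never silently retried.
* `ks_normality()`: KS distance against a normal with estimated
  parameters, with a Monte-Carlo (Lilliefors-style) null — the naive KS
  p-value is anti-conservative when parameters are estimated. The null
  distance distribution is parameter-free for the normal family, so
  standard normal draws suffice.

## Training and testing pipeline

`run_grid_search()` crosses {none, RW1, RW2} × {TU, TY} × hyperparameter
settings over stratified k-fold CV (default 10 folds; class counts per
fold differ by at most one row). Selection operationalizes "lowest
average EOD without significantly reduced performance" as: anchor on the
best-AUC configuration; keep configurations whose paired across-fold AUC
difference from the anchor is non-significant at α = 0.05 *or* within a
non-inferiority margin of 0.01 AUC (the fallback matters for tiny grids
where a paired t on few folds has no power); among the survivors pick the
smallest |mean EOD|; break ties by grid order. Signed EODs are averaged
first and the absolute value taken after, so systematic disparities in
opposite directions across folds do not masquerade as fairness — but the
audit table reports the signed mean.

`run_test_phase()` draws `n_boot` stratified bootstrap replicates (with
replacement, 80% of each outcome stratum by default) of the disjoint
test split. `frac = 1` means "the whole split, once, no resampling", so a
single full-fraction replicate reproduces direct evaluation exactly — the
identity the protocol-fidelity test asserts. Replicates in which a race
group loses all its positives are redrawn and counted. An earlier design
used without-replacement subsampling at all fractions; its percentile
intervals were about half the correct width (finite-population
shrinkage), which showed up as under-coverage of zero EOD on unbiased
data, and it was replaced.

## The synthetic cohort generator

The generator emulates the *structure* the framework assumes, not any
real dataset: ~4.12% outcome prevalence, ~5.74% minority share, group
base rates 4.44% / 4.10% (close enough that a two-proportion z-test does
not separate them at trial scale), and the feature schema of risk-based
eligibility models — age (truncated normal on the 55–74 enrollment
window), ordinal education, BMI, smoking status (38% current), pack-years
(intensity gamma(1.8, 0.55) packs/day × duration), years smoked tied to
age and start age, quit time gamma(1.4, 13) for former smokers, and
aggregated binary flags (COPD = bronchitis ∨ emphysema;
personal health history = family history ∨ prior cancer ∨ chest X-ray
history). The smoking marginals were set so the USPSTF-2021 comparator
has a realistic operating point on synthetic non-cases (specificity
~0.5 rather than ~0.2); with nearly-universal rule eligibility the
specificity-matched threshold degenerates (minority TPR pinned at 1).

Outcomes follow a logistic model in fixed-scale standardized features.
Group intercepts are calibrated by monotone bisection
(`calibrate_intercept()`, tolerance 1e-3 on the recovered probability,
Monte-Carlo sample of 100,000 linear predictors) so each group hits its
configured base rate. The coefficient scale is frozen so the *true*
linear predictor discriminates cases at AUC ≈ 0.80, the working point of
published lung-cancer risk models — this gives model-recovery tests an
oracle to converge to.

Race enters the default model feature set. Published risk models do use
race as a covariate, and in synthetic data with race independent of all
other features it is the only channel through which an injected
race-outcome association is learnable — and hence removable by
reweighing. Pass your own `features` vector to exclude it.

Three bias mechanisms compose freely (`bias_spec()`), all acting on the
minority group: a recorded-feature shift (measurement bias; outcomes are
drawn from the *true* features), a group intercept (true base-rate
difference), and differential label noise (under-ascertainment:
true positives recorded negative). They play different roles: parity
reweighing cleanly removes the spurious association created by label
noise, while a true group-intercept difference violates the equal-base-
rates assumption and is overcorrected — the generator makes both regimes
available precisely so that distinction is testable. The end-to-end
mitigation property is therefore exercised under label-noise bias (40%
of majority-group cases unrecorded), where the selected reweighed
configuration beats the matching unmitigated one in at least 8 of 10
seeded worlds while staying within 0.02 of the best CV AUC. A further
honest difference from real screening data: the rule-based comparator
itself shows little EOD in these worlds, because the synthetic bias
enters through labels that only the learned models consume, whereas
real rule-based criteria encode their own disparities.

One global integer seed drives everything through fixed substreams
(cohort draw, calibration, each sub-ensemble, each bootstrap stage), so
every fixture, fit and report is byte-reproducible; determinism is
asserted at each layer.

## Problem sizes

The test suite runs cohorts up to 200,000 rows for calibration checks,
20,000 for model recovery (EEC at 10 × 50), ten 40,000-row worlds for the
end-to-end mitigation property (logistic arm, 5 folds), 1,000 random
instances for threshold-enumeration equivalence, and 1,000 simulations
for t-test calibration; the full suite completes in about three minutes
on one CPU. The acceptance script uses two disjoint 40,000-row cohorts,
5-fold CV, both model arms, and 500 bootstrap replicates.

## Limitations

* Binary race and binary gender only; the reweighing machinery is
  general over attribute tuples, but the EOD reporting and the generator
  assume two race levels.
* Parity-based reweighing is the wrong tool when true base rates differ;
  the package surfaces this (z-test, overcorrection visible in the audit
  table) but does not implement error-rate-disparity alternatives.
* The bootstrap-replicate t-test inherits the published protocol's
  optimistic independence assumption; interpret p-values jointly with
  g_rm and CL.
* Synthetic cohorts have independent features within groups (no
  age-smoking-comorbidity correlation structure beyond the construction
  above), no missingness, and no survival/time-to-event structure, so a
  green suite demonstrates correctness of the machinery and
  direction-of-effect under controlled bias — not performance on any
  real population.
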