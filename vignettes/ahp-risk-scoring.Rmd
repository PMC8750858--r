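---
title: "Automatic AHP risk scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic AHP risk scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahprisk)
```

## The problem

Community follow-up programmes for schizophrenia accumulate long, noisy
records per patient: demographics, treatment state, adverse reactions,
hospitalization history, regional and calendar context, and occasional risk
events (hospitalization or referral, behaviour endangering others, loss of
insight, suicide or death). Clinicians want a single interpretable risk
score per patient-course that (a) reflects both data-driven effect sizes
and an expert-auditable factor structure, and (b) is insulated from
calendar artefacts such as policy-driven jumps in event reporting.

`ahprisk` implements that scoring pipeline around the analytic hierarchy
process (AHP). AHP organises the risk factors into a tree — a single
"risk score" target over the main criteria *Demography*, *Treatment* and
*Disease course*, each holding leaf factors bound to dataset variables —
and derives factor weights from pairwise comparison matrices. What is
usually an elicitation exercise is here automated: the comparison matrices
are generated from Cox proportional-hazards coefficient magnitudes,
quantized to the Saaty scale, consistency-tested and repaired, and solved
by power iteration.

## The AHP core

For factors $i, j$ under one parent, the comparison matrix entry $a_{ij}$
estimates the importance ratio $w_i / w_j$ on Saaty's discrete 1–9 scale
(grades 1, 3, 5, 7, 9 and the even intermediates, plus reciprocals).
A matrix is *consistent* when $a_{ij} a_{jk} = a_{ik}$; then its principal
eigenvalue $\lambda_{\max}$ equals its order $n$ and the normalized
principal eigenvector recovers the weights exactly. Real (and quantized)
matrices are inconsistent, measured by

$$CI = \frac{\lambda_{\max} - n}{n - 1}, \qquad CR = \frac{CI}{RI(n)},$$

with $RI$ the standard random index for orders up to 9
(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45). A matrix passes when
$CR < 0.10$. Orders 1–2 are consistent by construction ($CR \equiv 0$);
orders above 9 are rejected, which is why the default hierarchy keeps
every node at 9 or fewer children.

Weights come from power iteration (L1-normalized iterates, tolerance
1e-10, at most 10,000 steps; a 3–9 order reciprocal matrix converges in
tens of steps). The classical estimate
$\lambda_{\max} \approx \frac{1}{n}\sum_i (AW)_i / W_i$ is kept as a
cross-check; it is exact on consistent matrices and a dense eigensolver
is used as the independent oracle in the test-suite only.

Three choices were genuinely open:

* **Quantization.** Ratios snap to the nearest admissible value in
  log-space, so $x$ and $1/x$ quantize reciprocally; ties break toward 1
  (the conservative "less different" judgement).
* **Repair.** The acceptance rule says inconsistent matrices must be
  adjusted, without prescribing how. `repair_matrix()` iteratively
  replaces the entry most at odds with the current principal eigenvector
  (largest $|\log(a_{ij} w_j / w_i)|$) by the admissible value nearest
  $w_i / w_j$, re-testing after each edit, at most 50 rounds. Repairs
  never leave the Saaty grid when the input was on it.
* **Combination consistency.** The hierarchy-level test aggregates
  weighted per-matrix indices, $CR_{comb} = \sum_k g_k CI_k / \sum_k g_k RI_k$
  over internal nodes $k$ with global weight $g_k$, against the same
  0.10 bound — the standard hierarchic extension of the single-matrix test.

```{r ahp-demo}
A <- matrix_from_weights(c(0.55, 0.30, 0.15), quantize = TRUE)
A
consistency_report(A)
```

## From data to weights: the estimator

`ahp_risk()` is the single fitting entry point. Given one row per
patient-course it:

1. splits the rows 2:1 into stratified training and test parts;
2. ranks the leaf factors with the six-indicator importance ensemble
   (information gain, gain ratio, Gini reduction, Pearson chi-square,
   ReliefF, FCBF symmetric uncertainty; mean rank across indicators,
   undefined cells excluded rather than imputed);
3. discretizes continuous leaves (below);
4. fits a Cox proportional-hazards model (Breslow ties) of the event time
   on the leaves and turns coefficient magnitudes $|\beta|$ — normalized
   to sum 1 — into leaf seed weights, so protective and harmful effects
   contribute symmetrically; hazard ratios with 95% intervals are
   reported alongside. An optional significance filter (off by default)
   zeroes factors with $|z| < 1.96$ before seeding;
5. builds, quantizes and repairs the per-node comparison matrices and
   synthesizes leaf global weights (products of local eigenvector weights
   along the root path; they sum to 1 by construction);
6. scores each leaf level by its training-set empirical log-odds of the
   event, min–max normalized within the leaf to [0, 1] — the
   "multidimensional patient rating scale". The patient score is the
   weight-by-score inner product, bounded in [0, 1];
7. picks the classification threshold maximizing class-weighted F1 on the
   training scores (candidates are the observed scores, ties to the
   lowest, so strictly monotone rescalings leave the classification
   unchanged).

Reported metrics are AUC (midrank statistic), accuracy, and
class-weighted precision/recall/F1; under class weighting the reported
accuracy and recall coincide, which is the structure this harness is
meant to reproduce. Metrics are reported for both splits because which
slice headline numbers should come from is ambiguous in general.

Design notes worth recording:

* Level scores use log-*odds*, not log-rates. For a leaf whose level
  rates are 0.1/0.2/0.4 this gives scores (0, 0.45, 1), not (0, 0.5, 1);
  the two agree as rates get small. Rates are smoothed by $0.5/n$ before
  the logit.
* A leaf observed at a single training level carries no information and
  scores a constant 0.5 (with a warning), keeping its weight from
  distorting the bounded score.
* At scoring time a missing leaf value imputes the training-majority
  level (follow-up records are sparse); a level never seen in training is
  an error by default, while the fitted model object clamps
  numeric-labelled (count/ordinal) levels to the nearest training level.

## Supervised discretization

Continuous factors (age, durations, counts) affect risk non-linearly, so
they are discretized against the outcome before scoring. The
implementation seeds 20 equal-frequency bins and merges adjacent bins
bottom-up while their event rates are statistically indistinguishable by
a pooled two-proportion z-test; surviving cuts are then relocated to the
maximum-likelihood two-piece split point within their flanking bins, and
the merge test re-runs (at most 5 merge–refine rounds, which in practice
converges in 2–3).

Because the refined cut is a *maximally selected* statistic and up to 19
adjacent pairs are tested, the $(1-\text{confidence})$ error budget is
Bonferroni-split over roughly the square of the seed-pair count. At the
default confidence 0.95 this keeps the family-wise chance of any spurious
surviving cut in the low percent range while leaving real rate steps
(which carry z statistics an order of magnitude above the critical value)
untouched: on simulated two-piece hazards at $n = 5{,}000$ the scheme
recovers exactly two bins with the cut within ±2 units of the true change
point in ≥95 of 100 replicates, and three-piece hazards similarly. A
simple CI-overlap merge was tried first and rejected: the seed bin
straddling a change point has a genuinely intermediate rate, fails to
overlap either neighbour, and survives as an orphan bin.

Bins are half-open $[lo, hi)$ with the last bin closed, everywhere they
are serialized; every bin must hold at least `min_frac` (default 5%) of
the rows; each bin carries its Wilson interval and a nomogram-style score
(log-odds relative to the marginal rate). Lowering the confidence
produces narrower tests and therefore never fewer bins.

```{r disc-demo}
set.seed(1)
x <- runif(3000, 18, 80)
y <- rbinom(3000, 1, ifelse(x < 50, 0.06, 0.22))
supervised_discretize(x, y, variable = "age")
```

## Survival weighting and the age-period-cohort adjustment

The Cox step is a standard partial-likelihood fit (the `survival` package,
Breslow tie handling — ties are rare in the synthetic day-scale times and
the choice is immaterial there). Its proportional-hazards assumption is
exactly the generator's data-generating process; on real registries it is
an approximation the coefficient table lets you audit.

Calendar effects are removed with an age-period-cohort (APC) model on the
age-group × period grid of event counts with person-year exposures:
Poisson counts with log-exposure offset, age and period as sum-to-zero
fixed effects and the cohort (period index − age index) as a random
intercept, fitted with `lme4::glmer`. The random cohort axis is what
breaks the exact collinearity age + cohort = period; a ridge-penalized
fixed-effects approximation was considered and dropped because a full
mixed-model solver is available and matches the stated model directly.
`period_adjust()` then divides rates (or scores) by the exponentiated
fitted period effect, which removes policy-driven jumps while preserving
within-period orderings; on a simulated pure period step the adjusted
period trend is flat to within a slope of 0.02.

## The synthetic cohort

The registry behind this design is access-restricted, so the package
ships a generator that emulates its statistical structure rather than any
real records; every test and the acceptance experiments run on it.
`generate_cohort()` draws the full covariate schema (region, age and age
rating, gender, education, disability rating, social function, economic
status, compliance, adverse reactions, drug combinations, hospitalization
and referral history, poverty flags, diagnostic type, course duration,
calendar period, follow-up duration) from declared marginals, then event
times from an exponential proportional-hazards model whose linear
predictor combines:

* the default coefficient set (e.g. compliance 0.48, female gender
  −0.37, diagnostic type 0.61, social function 0.25) — the ground truth
  the Cox step is expected to recover at $n = 20{,}000$ to within ±0.04;
* five region offsets spread over ±0.5 log-hazard;
* a +0.3 log-hazard policy step from 2015 onward.

Records are administratively censored at their follow-up duration. The
exponential baseline rate is calibrated by root-finding so the realized
event prevalence matches the 15% default — the prevalence itself is a
declared default, not an empirical claim. Identical parameters and seed
reproduce the cohort byte for byte.

What the generator does **not** emulate: repeated measures per patient
(one row per patient-course), within-patient covariate correlation
structure beyond independence, non-proportional or time-varying hazards,
informative censoring, measurement error and the real marginals of the
restricted registry. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, not that it attains any
particular performance on real follow-up data; headline metrics from the
restricted registry are out of reproduction scope by design.

## Baseline harness and matching

`run_baselines()` runs the seven standard classifiers the score is
compared against — random forest (1000 trees, 5 attributes per split),
a 100-neuron single-hidden-layer network, ridge logistic regression
(C = 1), elastic-net logistic regression, kNN (K = 9, Euclidean,
uniform), RBF SVM (C = 1, γ = 0.1) and Gaussian naive Bayes — through the
identical metric harness and threshold rule. Two configurations are
mapped onto the R ecosystem: the stochastic-gradient elastic-net logistic
model is fitted by glmnet's coordinate descent, and the network's
Adam/learning-rate settings map to `nnet`'s BFGS optimizer with weight
decay; the regularization strengths and sizes are kept as configured.

`propensity_match()` pairs cases to controls 1:1 without replacement,
consuming admissible pairs globally closest first within a caliper of
0.2 pooled standard deviations (the common convention). Closest-first
consumption was chosen over per-case greedy order because the latter
leaves a systematic one-sided residual when the groups are shifted; on a
shifted-Gaussian simulation at $n = 2{,}000$ the post-match standardized
mean difference is below 0.01.

## Problem sizes and determinism

The shipped tests and acceptance experiments use: 100 random hierarchies
per order 3–7 for the consistency battery; $n = 20{,}000$ for coefficient
recovery; a 20 × 10 age-period grid at 1,000 exposure per cell for the
APC step; 100 replicates of $n = 5{,}000$ for discretization recovery;
and a 2,000-row cohort for the end-to-end run — sizes at which every
recovery tolerance stated above is met while a full run of the suite
stays interactive. All randomness flows through explicit seeds; the
pipeline writes a manifest (config hash, seed, stage list) sufficient to
reproduce a run exactly.

## Known limitations

* Single-judge AHP only: no group aggregation, fuzzy extensions or ANP
  networks; matrices stay on the Saaty grid during repair.
* The blending rule between expert edits and learned weights is exposed
  only as a manual hook (edit the hierarchy's weights or matrices and
  refit); no semantics are imposed on how the two should be reconciled.
* Binary any-event outcome; the four risk-event types are collapsed and
  competing risks are not modelled.
* No time-varying covariates, frailty terms (beyond the cohort random
  effect) or Efron tie handling.
* The propensity matcher materializes the case × control distance
  matrix; it is meant for cohort-scale (10^3–10^4) matching, not
  registry-scale.
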