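---
title: "Explainable tree-ensemble mortality models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable tree-ensemble mortality models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package does

`treemort` is a toolkit for studying all-cause mortality (or any binary
clinical endpoint over a fixed follow-up horizon) with gradient-boosted
decision trees (GBTs) and exact Shapley-value explanations. A GBT scores a
subject in log-odds ("margin") space; the event probability is the logistic
transform of the margin. Around that core model the package provides four
analyses that are usually done ad hoc, here implemented as tested, reusable
operations:

1. **Additive attribution.** For every subject, the model margin is
   decomposed as `base + sum_j phi_j`, where `phi_j` is the exact Shapley
   value of feature *j* in the interventional coalition game: out-of-coalition
   features are replaced by values from a background sample and the model
   margin is averaged. A pairwise interaction tensor refines each `phi_j`
   into a main effect (the diagonal) plus symmetric interaction halves whose
   row sums reproduce `phi`.
2. **Supervised distance.** A task-aware redundancy metric between features:
   train a univariate GBT of the label from feature *i* (output
   `P_i`), train a second univariate GBT of `P_i` from feature *j*, and set
   `R2(i,j) = max(0, 1 - mean((P_i - P_i^j)^2 / var(P_i)))`,
   `distance(i,j) = max(1 - R2(i,j), 1 - R2(j,i))`. Zero means the two
   features carry the same information about the outcome; one means none
   shared. Complete-linkage clustering of the distance matrix surfaces
   redundant groups, and a recursive selection procedure keeps each cluster's
   most important member (by mean |phi|) while always retaining age and sex.
3. **Reference-interval audits.** For a laboratory feature, the relative-risk
   curve `r(v)` fixes the feature at `v` for all subjects and divides the
   mean predicted probability by the unmodified mean. The relative risk
   percentage of a reference interval,
   `RRP = 100 * (max r inside the interval - 1) / (max r overall - 1)`,
   saturates at 100 when the interval contains the model's risk maximum and
   is negative when risk inside the interval stays below the cohort average.
   High RRP flags an interval that admits high-risk values as "normal".
4. **Tiered risk scores.** Recursive feature elimination by mean |phi|
   builds small models from role-restricted pools (public: no laboratory
   features; professional: demographics plus laboratory; panel: a named
   list), each evaluated by bootstrap AUROC overall, per sex, and on
   held-out later enrollment cycles (temporal validation). Individual
   explanations re-express attributions in probability space.

## The synthetic cohort generator

Because real survey data cannot ship with a package, every analysis is
exercised against a generator whose ground truth is known exactly. A
`cohort_spec()` fixes:

* **Marginals.** `age` uniform on 18–85 years; `sex` Bernoulli(0.5);
  continuous analytes Normal(5, 1) by default (lognormal and uniform
  marginals available). Units are arbitrary "lab units" — the methods only
  see ranks and thresholds.
* **Planted effects** on the log-odds scale: monotone (`w * z`), U-shaped
  (`w * c * ((v - v0)/sd)^2`, zero at the optimum `v0`), saturating
  threshold (a ramp reaching `w * plateau` at the knot `v_t`, exactly
  constant above it), and multiplicative interactions
  (`w * z * z_partner`).
* **Redundancy groups**: members are distinct monotone transforms of one
  shared standard-normal latent plus independent noise (default sd 0.05 on
  the standardized scale), emulating anthropometric blocks such as arm
  circumference / BMI / waist / weight.
* **The mortality mechanism.** `logit p_h = beta0 + shift_h + sum(effects)`,
  one shift per follow-up horizon (defaults −1.2, −0.5, 0, +0.8 for 1, 3, 5,
  10 years). A single uniform draw per subject is compared against the
  increasing probability sequence, so labels nest across horizons the way
  real follow-up deaths do. The default baseline `beta0 = logit(0.03)`
  puts the realized 5-year event rate near 15–20% once the (mostly
  risk-increasing) planted effects are added — a deliberately event-rich
  synthetic regime that keeps test cohorts of a few thousand subjects
  informative.
* **Missingness** is MCAR at a configurable rate (default 5%) on all
  non-demographic features; tree learners receive missing values natively,
  and only the linear baseline median-imputes. The generator does not
  emulate informative missingness, survey weights, cycle-specific drift, or
  measurement error — so passing tests demonstrate correct mechanics and
  recoverability of planted structure, not robustness to those real-data
  complications.

`default_cohort_spec()` is the reference condition used throughout the
tests: an age effect (w = 1.2), a U-shaped urate effect with its optimum at
4.6 (off-center, so the high-risk tail is unambiguous), a urine-albumin
threshold at 5.8, monotone red-cell-distribution-width and blood-lead
effects, an age-by-lead interaction with negative weight (the exposure harms
the young more), a four-member anthropometric redundancy group whose
`arm_circumference` member is protective, and eight noise questionnaire
features. Scales of 4,000–6,000 subjects keep every analysis comfortably
under a minute while leaving planted signals recoverable.

### Planted reference intervals

For each feature with a substantial main effect (|weight| ≥ 0.5 among
non-interaction terms) the generator derives two intervals from the *true*
relative-risk curve: an **optimal** interval covering the clearly-low-risk
run around the risk minimum (relative risk at most `1 - 0.33 * (1 - r_min)`,
a buffer below the cohort-average line so that estimation noise at the
`r = 1` crossing cannot spill risk into the interval), and a deliberately
**mis-set** interval covering the high-risk run around the risk maximum
(relative risk at least halfway from the average line to the maximum,
expanded by a few grid steps). Interaction-dominated features are excluded:
their risk profile depends on the partner, so no single-population interval
is meaningful.

## Numerical and algorithmic choices

* **Attribution engine.** Exact interventional Shapley values are computed
  in compiled code by a leaf-wise decomposition: for one foreground row and
  one background row, each leaf's reachability is a conjunction over the
  "distinguishing" features on its path (those routed differently by the
  two rows), and Shapley values of conjunction games have closed forms. The
  engine works off the booster's text dump in double precision and mimics
  the learner's single-precision split comparisons, so additivity
  (`base + sum(phi) = margin`) holds to machine precision and the engine
  agrees with a brute-force `2^d` enumeration oracle (which goes through the
  booster's own predictions, an independent code path) to well below 1e-6.
  The default background is a fixed 100-row subsample of the training set
  chosen at fit time.
* **Probability-space explanations.** Individual risk-score explanations
  rescale the log-odds attributions proportionally by
  `(risk - base_risk) / sum(phi)`, so the contributions plus the mean
  training risk reconstruct the subject's risk exactly. This is a
  documented approximation: it preserves each feature's relative share
  rather than re-deriving Shapley values of the probability-scale game.
* **Hyperparameters.** The full grid-search default explores depth {3, 6},
  learning rate {0.1, 0.05}, rounds {100, 500} and minimum child weight
  {1, 10} with stratified 5-fold cross-validated AUROC, ties broken by grid
  order. Test and pipeline refits use a fixed single-point grid (depth 3,
  eta 0.1, 100–250 rounds) for determinism and speed. Univariate
  supervised-distance models use the learner's default hyperparameters; the
  boosting-round count, which the library leaves to the user, is fixed at
  50.
* **Supervised distance conventions.** `P_i` is taken in probability space
  by default (margin space is available); the variance in the R² denominator
  is the population variance, so a constant `P_i` (a feature carrying no
  label information) yields R² = 0 and distance 1 rather than an exception.
  Distances are computed on the training split only, cached per feature
  pair, and reused across selection iterations, while the clustering itself
  is rerun on each surviving feature set.
* **AUROC.** The Mann–Whitney rank form (ties counted one half), verified in
  the tests against brute-force pair counting and against an established ROC
  implementation. Bootstrap intervals are percentile intervals over seeded
  subject resamples; replicates that lose one class are dropped.
* **RRP.** The formula above is a reconstruction: it reproduces the intended
  qualitative behaviour (negative values possible, saturation at exactly
  100 when the interval holds the risk maximum, "higher = more
  inappropriate"). The maximum — rather than mean or boundary — relative
  risk inside the interval is used, consistent with the saturating behaviour
  of audits on clearly mis-set intervals. Numerical ties with the global
  maximum are snapped to exactly 100. The flag threshold defaults to
  RRP > 50%.
* **Seeding.** Every stochastic step (simulation, splits, fold assignment,
  background subsampling, bootstraps) is seeded; the pipeline fans one root
  seed into per-stage seeds, and reruns with the same configuration
  reproduce identical artifact hashes.

## Known limitations

* Interaction tensors cost `O(n_fore * n_back * leaves * depth^2)` and are
  intended for subsamples (a few hundred subjects), not whole cohorts.
* The supervised distance inherits the variance of its univariate fits: with
  a few thousand subjects, noisy members of a redundancy group sit at
  distances around 0.6 rather than near 0, while unrelated features sit
  above 0.9. Group structure is recovered by the *contrast*, not by absolute
  values near zero.
* The logistic baseline is a deliberately plain comparison (ridge penalty,
  median imputation, no transformations); it is not a state-of-the-art
  linear survival model.
* Relative-risk curves are raw partial-dependence estimates; occasional
  step artifacts in sparse tails are visible at the audit stage, which is
  why the planted intervals carry buffers.
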