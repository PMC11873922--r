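---
title: "Modelling frequent A&E attendance with synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frequent A&E attendance with synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facohort)
```

## The problem

Frequent attendance (FA) at accident and emergency departments — three or
more visits a year as the inclusion floor, five or more as the common FA
definition, more than ten as High Intensity Use — concentrates a large
share of emergency workload in a small group of patients. Stratifying that
risk from routinely collected health and social care data supports
targeted early intervention. Patient-level A&E records are not shareable,
so this package makes the entire analysis reproducible on *synthetic*
cohorts that are calibrated to the published summary statistics of a real
one-year health-board cohort and that plant known risk-factor effect
directions, letting every downstream stage (weighting, the five
classifiers, evaluation, Shapley attribution) be exercised and tested
without any data access.

## The synthetic cohort generator

A cohort is a table of one row per patient: demographics (gender, six age
groups, SIMD deprivation quintile), service-use counts (home care, acute
and mental-health inpatient, self-harm, substance-misuse and alcohol
episodes), ten long-term-condition (LTC) flags with their sum, and the
target — the number of A&E attendances `v >= 3`.

The generator composes four stages under one seeded RNG stream, in a fixed
documented order (features, then class assignment, then visit counts), so
a configuration plus seed determines the cohort bit-for-bit:

**Moment calibration** (`calibrate_count_distributions`, deterministic).
The attendance distribution is a three-part mixture: the low class is
pinned at the published composition (9,730 patients with exactly three
visits and the remaining 3,744 with four); the mid (5–10 visits) and high
(11+ visits) classes get count distributions solved so the full mixture
has mean 4.14 and SD 2.81 visits. Both conditional distributions come from
a shared two-parameter exponential-quadratic family
$p(v) \propto \exp(a v + b v^2)$ on their supports. Two parameters against
two moment constraints makes the solve well-posed; the family spans
everything from geometric-like decay to bimodal extremes, so it can reach
the required heavy tail (the high-class support runs to `max_visits = 60`
— without that tail the mixture cannot reach SD 2.81 given the mass at
3–4 visits). The solver (Nelder–Mead refined by BFGS on scaled squared
residuals, multi-start) reaches residuals of order 1e-18; arithmetically
infeasible targets raise a calibration error naming the violated moment.
The published moments are under-determining — any within-class family
matching them is admissible — and this family was chosen once for
smoothness and feasibility, not fitted to data.

**Feature drawing** (`generate_features`). Binary flags are Bernoulli,
ordinals categorical, episode counts negative-binomial (over-dispersed,
matching the sparse right-skew of service-use counts). The SIMD marginal
is skewed towards quintiles 1–2 (70% of mass), reflecting the strong
deprivation gradient reported for frequent attenders. `total_ltcs` is
always computed from the flags, never drawn. Marginal parameters are
frozen defaults chosen to be clinically plausible (e.g. 4% deceased, 3%
homeless, mean 0.6 acute episodes); they are knobs of the study
conditions, not fitted quantities.

**Class assignment** (`assign_classes`). Each patient gets a latent risk:
a linear combination of standardised features with signed effect
coefficients plus unit Gaussian noise. The top 348 (scaled) risks become
the high class, the next 3,615 the mid class, the rest low — rank-based
assignment makes the printed class sizes exact for every seed and
decouples count calibration from effect planting. The default
coefficients carry the consensus effect directions (acute inpatient
episodes strongest positive at 1.0; age group −0.6; SIMD quintile −0.55;
digestive +0.5; alcohol +0.45; down to ±0.05). Magnitudes were fixed once
so that all five model families recover the leading signs, and are
documented as part of the frozen defaults; features with |coefficient|
≥ 0.25 have their class-contrast sign guaranteed (19/20 seeds) at the
default cohort size.

**Visit counts** (`draw_visit_counts`). Each class's visit-count histogram
is fixed at the calibrated expected counts (largest-remainder rounding)
and randomly permuted among the class's rows — the same exact-count scheme
the low class uses for its 3s and 4s. Independent draws were considered
and rejected: with only 348 patients carrying the 11–60 tail, iid sampling
makes the cohort SD swing by ±0.2 across seeds, defeating the calibration;
quota realisation keeps mean and SD within rounding of the targets for
every seed, at the cost of suppressing sampling variability in the
histogram itself (only the patient-to-count assignment is random). This is
the main respect — along with independent feature marginals and a purely
additive latent risk — in which the generator is *less* variable than real
data: passing tests demonstrate correctness of the machinery under planted
conditions, not performance on real records.

## Pre-modelling

`bin_attendance` maps counts to the three classes (<5 → 0; 5–10 → 1;
>10 → 2), rejecting counts below the inclusion floor of 3.
`compute_sample_weights` implements inverse-class-frequency weighting in
the balanced convention $w_c = N/(K n_c)$ ($K = 3$; the source states
proportionality only, and this normalisation keeps $\sum_i w_i = N$), and
visit-value weighting $w_i = v_i/\bar v$ with the training-cohort mean as
normaliser so loss magnitudes stay comparable to unit-weight training.
`split_train_test` defaults to a seeded, non-stratified 70/30 split: the
published test totals (5,232 of 17,437) match 30% overall but deviate from
exact per-class 30%, which is consistent with a non-stratified draw; the
protocol was otherwise unstated, so the choice is exposed as parameters.
`encode_features` standardises with train-fitted centre/scale (test rows
transformed with the same parameters; zero-variance columns get scale 1
with a warning) and retains raw matrices because occlusion semantics live
in raw space.

## The model suite

`model_spec` + `fa_fit` wrap five families behind one probability
contract $p_c(x)$, rows summing to 1:

* **LR** — `nnet::multinom`, iteration cap 100,000. The reference
  implementation used L-BFGS; `nnet` optimises by BFGS, the same
  quasi-Newton family (the limited-memory variant matters only for much
  larger parameter spaces than 23 features × 3 classes).
* **RF** — `ranger`, 100 trees, Gini splits, probability forest, case
  weights, fitted on raw features (splits are scale-invariant).
* **SVM** — `e1071::svm`, RBF kernel at default settings (cost 1, kernel
  width $1/d$ on standardised inputs, equivalently $1/(d\,\mathrm{Var})$);
  a grid search was reported to degrade ranking performance, so defaults
  are deliberate. Class weights carry the inverse-frequency weighting;
  `probability = TRUE` provides cross-validated sigmoid calibration,
  satisfying the held-out-calibration contract that ROC analysis needs.
* **k-NN** — k = 18, Euclidean distance in standardised space,
  probabilities as neighbour class fractions. Implemented directly because
  the available library routine returns only the winning class's vote
  share, while ROC and the expected-class risk score need full
  three-class rows. Vote ties resolve to the smallest class index;
  distance ties resolve by training-row order. k-NN has no native sample
  weighting and is fitted unweighted.
* **MLP** — authored in base R matrix operations (`train_mlp`): hidden
  layers (default 64, 32) with batch normalisation, ReLU and dropout
  (0.2), softmax head, L2 1e-4 / L1 0, mini-batch 256, up to 200 epochs
  with early stopping (patience 20) on a 15% validation split. The
  optimiser is Adam at learning rate 1e-3 — chosen over plain SGD for
  robustness at small batch counts; the loss landscape, not the optimiser,
  is the object of interest. With no hidden layers the network reduces to
  softmax regression, which the tests exploit as an oracle.

### The value-hot focal loss

The MLP trains on
$$L_i = \frac{v_i}{\nu}\,(1 - p_{i,c_i})^{\gamma}\,(-\log p_{i,c_i}),$$
the canonical composition of two imbalance devices: the *value-hot*
weight replaces the one-hot indicator with the patient's actual
attendance count (normalised by $\nu$, default $\bar v$), so a
misclassified 40-visit patient costs ten times a misclassified 4-visit
patient; the *focal* factor ($\gamma$, default 2, the focal-loss
convention) down-weights examples the model already classifies well. With
$\gamma = 0$ and $v_i \equiv \nu$ the loss is exactly cross entropy
(tested to 1e-12), and its analytic logit gradient — used by
backpropagation — is verified against central finite differences to 1e-5.
True-class probabilities of exactly zero are clamped at 1e-12 with a
warning rather than silently.

## Evaluation

`confusion_matrix` (rows = actual), `classification_metrics` (per-class
one-vs-rest precision/recall/F1), and `roc_curve_ovr` (tie-grouped
thresholds, trapezoidal AUC; cross-checked against `pROC` in the tests).
Because the aggregation convention behind published three-class summary
tables is often ambiguous, both macro and support-weighted aggregates are
always emitted and labelled. Precision for a never-predicted class is 0
with a warning — the common tooling convention that keeps aggregates
finite. `auc_macro` is the unweighted mean of the three one-vs-rest AUCs.

## Shapley attribution

All methods attribute a scalar risk score; by default the expected class
$s(x) = \sum_c c\,p_c(x) \in [0,2]$, which yields one signed value per
feature as consensus risk-factor tables report (a per-class probability
mode is available; which output published tables used is not stated, so
the scalarisation is an explicit, documented choice).

* `zero_input_importance` — occlusion: $\phi_j$ is the mean score drop
  when feature $j$ is set to 0 for all rows. Zeroing happens in *raw*
  feature space before re-standardisation: zero means "absent". In
  standardised space it would mean "at the cohort mean", a different and
  weaker counterfactual. Ordinals (age group, SIMD) are zeroed uniformly
  even though 0 is outside their coded range — the operation is applied
  uniformly to every feature, and the resulting extrapolation is flagged
  here rather than special-cased.
* `permutation_shapley` — Monte-Carlo Shapley: for each sampled feature
  ordering, not-yet-added features take background values (empirical
  per-feature marginal resampling by default, re-drawn per permutation;
  an all-zeros background matches the occlusion semantics), and $\phi_j$
  averages the score change when $j$ switches to its true values, over
  rows and orderings. Estimates carry per-feature Monte-Carlo standard
  errors and are seed-reproducible.
* `exact_shapley` — the validation oracle: full subset enumeration
  $\phi_j = \sum_{S} \frac{|S|!\,(d-|S|-1)!}{d!}\,[v(S\cup\{j\}) - v(S)]$,
  guarded at 12 features, scoring all $2^d$ coalition rows in one
  vectorised call. Efficiency holds by construction; the tests verify
  efficiency, dummy and symmetry to 1e-9, permutation convergence within
  3 Monte-Carlo SEs at 2,000 orderings, and the closed-form agreement of
  all three methods on additive scores with zero background.

`cohort_risk_factors` applies a method to the rows of a selected actual
class — low/mid attenders (which factors raise escalation risk) or high
attenders (which factors, if mitigated, would reduce attendance) — without
refitting the model (trained once, probed per cohort), filters at the
|φ| > 0.01 reporting convention, and ranks descending with name
tie-breaks.

## Pipeline and interfaces

`run_pipeline(pipeline_config(...))` chains generate/load → prep → fit →
evaluate → explain, writing the cohort CSV, split manifest JSON, one
evaluation JSON per family, combined confusion and metrics CSVs mirroring
the standard report layouts, risk-factor CSVs per family and cohort, and
a manifest with seeds and configuration; any stage failure aborts with
the stage name and leaves a `FAILED_<stage>` marker beside the partial
outputs. The package is used from R — the exported functions and this
pipeline are the interface, with `scripts/acceptance.R` as the
reproduction entry point; no shell CLI is shipped.

## Numerical choices and problem sizes

Degenerate and edge cases are handled explicitly: single-class label sets
refuse to fit; probability ties resolve to the smallest class index;
zero-variance columns standardise to zero with a warning; empty cohort
selections error; the exact oracle refuses more than 12 features;
non-finite MLP losses abort with diagnostics. The test suite runs its
end-to-end checks on cohorts of 500–4,000 patients with proportionally
scaled class structure (the calibration machinery is size-invariant, and
20-seed generator properties run at the full 17,437 default, which costs
well under a second per cohort); the cross-model sign-recovery check
trains all five families at n = 4,000. These sizes are the package's
chosen test conditions; the generator's defaults remain the full-scale
study conditions.

## Limitations

Synthetic cohorts have independent feature marginals, an additive latent
risk and quota-realised count histograms: they validate machinery, not
clinical performance, and published headline metrics on the real cohort
are not reproducible from them. Effect-coefficient magnitudes are
arbitrary up to the documented sign/strength contract. The value-hot
focal loss is implemented for the MLP only, as in the source analysis;
the other families use class-frequency weighting. Kernel SHAP and
interaction (second-order) attributions are out of scope.
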