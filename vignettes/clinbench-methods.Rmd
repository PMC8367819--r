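---
title: "Methods: benchmarking clinical tabular classifiers with graph-based matrix completion"
author: "clinbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking clinical tabular classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical registries collect mixed-type tabular data — continuous test
results, binary findings, categorical questionnaire items — with
substantial missingness and class imbalance. Before any single model is
put in front of clinicians, it is good practice to benchmark a broad
panel of classifiers under honest cross-validation and present the
outcome (metrics, confusion matrices, input-space structure, feature
importances and univariate statistics) as one reviewable report.
`clinbench` implements that workflow end to end for a patient-by-feature
table with a declared schema, including a from-scratch transductive
multi-graph geometric matrix completion (MGMC) classifier that handles
missing values natively.

## Preprocessing

Continuous features are 90% winsorized — values outside the 5th/95th
percentile of the fit data are clipped to those bounds — and then
z-transformed to zero mean and unit variance. Binary features become a
single 0/1 column (second declared category = 1); categoricals with
three or more levels are one-hot encoded. A feature observed in less
than half of the fit subjects is omitted entirely; every remaining
missing cell is mean-imputed with the fit-column mean (for one-hot
columns this yields fractional category frequencies, the literal
consequence of applying mean imputation uniformly).

Numerical conventions that are pinned so results are exactly
reproducible:

* percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`);
* standardization uses the population (1/N) variance;
* a zero-variance feature is flagged constant and emitted as all zeros
  with a warning rather than an error;
* winsorization and standardization never touch 0/1 encoded columns —
  clipping a bounded column is vacuous and rescaling it damages the
  interpretability of downstream importances.

Preprocessing is *fitted on the training portion of each outer fold
only* and applied frozen to the held-out fold. Fitting globally before
splitting leaks test-fold statistics into training; a `global` mode is
still available as a config switch for comparability experiments. The
transductive MGMC model is the stated exception: it receives the full
(un-imputed) matrix with the plan fitted on the training rows, but only
training labels — transduction concerns features, never labels.

## Cross-validation and tuning

Evaluation uses stratified k-fold cross-validation with k = 10: within
each class, subjects are shuffled by the seed and dealt round-robin to
folds (the deal offset carries across classes, so fold sizes stay
balanced and k = N degrades to leave-one-out). This yields exactly one
out-of-fold prediction per subject and ten metric estimates per
classifier. A class with fewer members than k degrades to a warning —
rare-disorder groups must still run.

Hyperparameters are tuned by random search nested inside each training
partition: `nIter` candidates (default 30) are sampled from each
model's search space, scored by the mean selection metric (default
accuracy) over 3 inner stratified folds of the training rows only, and
the best candidate is refitted on the full training partition.
Duplicate candidates are evaluated once; ties go to the earliest
sampled. Models with empty spaces (LDA, GNB, GP) skip the inner loop.
The master seed spawns an independent child stream per fold, model and
purpose via a polynomial hash, so adding a classifier to the registry
does not perturb the randomness of the others.

## The classifier registry

Eleven models, in their stated parametrizations: LDA (no shrinkage), L2
logistic regression, a linear SVC with squared-L2 penalty at cost 0.25
(class probabilities via logistic calibration of the signed margin,
fitted on training data — some calibration is unavoidable if ROC-AUC is
to be reported for every model), Gaussian naive Bayes with priors from
the data, a Gaussian process with RBF kernel whose length-scale is fit
internally, 10-nearest-neighbors under the Euclidean metric, a Gini
decision tree capped at depth 5, a random forest of 10 depth-5 trees
whose vote is the mean of per-tree class-probability vectors (our
reading of "confidence-weighted"), AdaBoost (multi-class SAMME) over
depth-1 stumps with at most 50 rounds, an MLP, and MGMC.

Search spaces are modest and centered on the stated defaults:
regularization strengths log-uniform on [1e-3, 1e3], k in {3, 5, 10,
15, 25}, tree depths in {3, 5, 8, 12}, forest sizes in {10, 50, 100},
boosting rounds in {10, 25, 50}, MLP learning rate log-uniform on
[1e-4, 1e-2], MGMC hidden size in {16, 32, 64}. Multi-class handling:
LR and SVC are one-vs-rest; the others are natively multi-class.

The MLP has hidden layers of 64 and 32 neurons, each
linear → ReLU → dropout (p = 0.3) → batch normalization, a softmax
head, cross-entropy loss and Adam, full batch, up to 200 epochs with
early stop on a training-loss plateau (tolerance 1e-4, patience 10).
It is written with explicit forward/backward passes; the same code
yields analytic input gradients for attributions.

## MGMC

MGMC treats classification as transductive matrix completion. Patients
are nodes in several graphs, one per meta feature: same gender, age
within ±6 years, EQ5D within ±0.06, DHI within ±11 (pairs with a
missing meta value get no edge). Features and one-hot labels form one
N × (d + C) completion matrix; the observed entries are the non-missing
cells plus the label cells of training rows. Each of 5 timesteps
applies order-5 Chebyshev filters of the scaled graph Laplacian
(`L~ = 2 L_sym / lambda_max − I`, isolated nodes zero rows), sums the
per-graph outputs, passes them through a single hidden layer (16/32/64
neurons, tuned per task), and updates the completion through a gated
recurrent cell with input and forget gates (an LSTM-style update
without an output gate; the forget bias starts at +1 so training begins
near the identity map). The loss is

* squared reconstruction error on observed feature entries (weight 1),
* graph smoothness `gamma * sum_g tr(M' L_g M) / (N (d + C))` with
  gamma = 1e-3,
* cross-entropy over training rows (weight lambda = 1), read off the
  label columns by softmax.

Adam runs at rate 0.02 for up to 500 epochs and stops once the mean
per-epoch improvement of the total loss over the last 25 epochs falls
below 2e-4 — a plateau window rather than a best-so-far counter,
because the reconstruction term keeps improving by tiny amounts long
after predictions have stabilized. The rate and tolerance were chosen
by profiling convergence on synthetic cohorts (predictions stabilize
within roughly 100 epochs at this scale); they are exposed in
`mgmcConfig()`.

Because the per-graph Chebyshev outputs are summed before the hidden
layer, the fixed matrices `A_k = sum_g T_k(L~_g)` are precomputed once
per subject set and the whole filter bank is a single matrix product
per timestep; the identity of this route with filtering each graph
separately is unit-tested. `lambda_max` is computed exactly for
N ≤ 2000 and by 50 power-iteration steps beyond. Test labels are
structurally excluded: the one-hot label block is built from training
rows only, so garbling held-out labels cannot change any output (this
is asserted, not merely assumed).

One behavior worth knowing: with a nonzero classification weight the
model may deliberately distort the reconstruction of strongly
class-informative columns toward a more discriminative representation —
reconstruction fidelity is only guaranteed for columns that carry no
label signal, and the tests check it there.

## Explanations

Per-classifier feature importances follow each family's native recipe:
mean absolute coefficients across one-vs-rest rows (linear models),
impurity-decrease importances (tree models), and mean Integrated
Gradients attribution of every training sample toward its ground-truth
class probability (neural models) — the softmax output is what a
classifier is read by, and its bounded scale keeps the path-integral
quadrature accurate — with a zero baseline, which after
z-transformation approximates the population-mean patient. KNN, GP and
GNB have no native recipe; they get seeded permutation importance
(mean accuracy drop over 5 shuffles), with the option to exclude them
instead. For the transductive model, attributions are computed on the
joint training score with the whole feature block scaled along the
straight path to the zero baseline — one batched backward pass per
Riemann step instead of one per sample, exact for the same reason the
per-sample path integral is.

Integrated Gradients uses the midpoint Riemann rule (50 steps by
default); for linear scores the closed form `w * (x − baseline)` is
recovered at any step count, and completeness
(`sum of attributions = f(x) − f(baseline)`) is verified against direct
evaluation on the MLP. The completeness gap of a ReLU network is pure
quadrature error at the gradient's kinks: it scales with the score's
total variation and decays like 1/steps, which is why the bounded
probability score is attributed rather than the raw logit (whose
midpoint-rule gap at 200 steps is several times 1e-3 for a 64/32 net
regardless of training length).

RAFI (relative aggregation of feature importance) merges the rankings:
take absolute values, normalize each classifier's vector to sum one,
and sum across classifiers; the total then equals the number of
contributing classifiers, and the aggregate is invariant to
per-classifier rescaling and sign flips. Per-fold importances are
averaged across the k outer folds before aggregation (the
fold-aggregation step is our choice; computing them on a single final
refit would be the alternative). One-hot columns are pooled onto their
source feature by summation before ranking, so the report names
clinical variables rather than encoding columns.

## Metrics and statistics

Accuracy, precision, recall and f1 follow the count-based definitions;
f1 is 0 where precision + recall is 0. For binary tasks the reported f1
and ROC-AUC refer to the minority class — under imbalance the minority
sensitivity is the clinically informative number — with macro variants
emitted alongside so either convention is reproducible. Multi-class
tasks report macro averages and one-vs-rest macro ROC-AUC. The AUC is
computed from the Mann-Whitney rank statistic with midranks, which is
exact under ties.

Per-feature hypothesis tests are routed as a clinician would expect:
chi-squared independence (no continuity correction) for categoricals,
with a warning when expected counts fall below 5; for continuous
features, Shapiro-Wilk normality at alpha 0.05 in every group decides
between t-test (two groups, pooled variance) or one-way ANOVA versus
Mann-Whitney U or Kruskal-Wallis. Groups larger than 2000 route
non-parametric directly. Significance is reported at raw p < 0.05; no
multiplicity correction is applied, by design of the reporting format.

The 2D panel embedding is UMAP (seeded, single-threaded for exact
reproducibility); cohorts under 10 subjects fall back to the first two
principal axes with a warning.

## The synthetic cohort generator

`synthConfig()` defaults emulate a two-class chronic-vestibular-style
task: 66 vs. 346 subjects, five informative continuous features at a
1 s.d. class shift, fifteen noise features, one informative binary and
one three-level categorical, 10% MCAR missingness, and meta features
with realistic class-conditional distributions (age about 65 ± 17 vs.
47 ± 15 years, gender mildly imbalanced, EQ5D 0.8 ± 0.2 truncated to
[0, 1], DHI around 45 ± 20 truncated to [0, 100]) so the MGMC graph
thresholds are meaningful out of the box. `permuteLabels()` provides
the leakage null: features untouched, labels shuffled.

What the generator does *not* emulate: correlated feature blocks,
missingness that depends on observed or unobserved values (MAR/MNAR),
questionnaire item structure, site effects, or label noise. Passing
tests on this cohort therefore demonstrate pipeline correctness —
leakage-free evaluation, recovery of planted signal, calibrated null
behavior — not clinical performance on any real registry.

## Problem sizes and runtime choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full pipeline exercises every code path in minutes:
benchmark checks use N = 400 (balanced) or the default 66/346 cohort
with k = 10 and 5 random-search candidates; the completion-recovery
experiment uses a rank-3 200 × 20 matrix with 30% of entries masked;
importance recovery plants 5 informative features among 50 over five
seeds; null calibration of the routed tests uses 2000 replicates of 50
subjects per group. Every random quantity derives from a single master
seed.

## Known limitations

* SVC probabilities are a calibration, not a likelihood; rankings (AUC)
  are meaningful, absolute probabilities less so.
* Permutation importance on strongly correlated features splits credit;
  RAFI inherits that property.
* The MGMC attribution explains the joint training score, which mixes a
  sample's own contribution with its influence on graph neighbors —
  that is the honest object for a transductive model, but it is not a
  per-sample explanation.
* The benchmark reports prospective-performance *estimates*; model
  selection across the panel after looking at the report introduces the
  usual winner's-curse optimism, which nested CV does not remove.
* Pooled out-of-fold accuracy on label-permuted data is overdispersed
  relative to a binomial draw: the k fold models share the permuted
  label vector and each fold's predictions share one fitted model.
  A leakage check that compares every classifier against a plain
  binomial interval around the majority rate therefore flags an
  occasional below-chance classifier on pure noise; genuine leakage
  shows up on the *upper* side of the interval.
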