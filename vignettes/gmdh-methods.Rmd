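---
title: "Methods: optimized GMDH classification of imbalanced mixed-type cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimized GMDH classification of imbalanced mixed-type cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmdhx)
```

# The problem

Screening questions in pediatric epidemiology often reduce to two-class
prediction from a mixed bag of measurements: interval-scaled clinical
variables (age, blood pressure), ordered and unordered categories (activity
level, family histories), and SNP genotypes coded as nucleotide pairs. Two
properties of such cohorts break off-the-shelf classifiers: the feature
scales are incommensurate, and the classes are imbalanced (a disease
prevalence around 40% is mild imbalance; many screening settings are far
worse). `gmdhx` implements a self-organizing polynomial network — a Group
Method of Data Handling (GMDH) classifier — wrapped in the preprocessing,
feature weighting, resampling and validation machinery that such data
require, plus the genetic-epidemiology statistics used to describe a
case-control cohort, and a synthetic cohort generator so the whole pipeline
is exercisable without access to any original patient data.

# The model

## Mixed-type mapping into [0,1]

All predictors are mapped to the unit interval before the network sees them.

* **Interval features** get a robust Z-score: subtract the training median,
  divide by the training MAD, then min–max rescale using the post-Z training
  range, clipping out-of-range test values. The MAD is the raw median of
  absolute deviations without the 1.4826 normal-consistency factor — the
  min–max step immediately absorbs any constant scale factor, so the factor
  is immaterial here.
* **Categorical features** (nominal and ordinal alike) are expanded to
  complete one-hot indicators; each indicator is then passed through a
  univariate logistic (logit) map whose intercept and slope are the maximum
  likelihood estimates of class-on-indicator regression. The single-indicator
  MLE has a closed two-cell form: `plogis(b0)` is the observed positive rate
  at indicator level 0 and `plogis(b0 + b1)` at level 1. Under complete
  separation or an empty cell, Jeffreys-style 0.5 pseudo-counts on the 2×2
  cells keep the coefficients finite and deterministic. Each mapped
  indicator thus carries an estimate of `P(case | indicator level)` — the
  categorical information expressed on the same [0,1] scale as the interval
  block.

Every mapping statistic is estimated on the training partition
(estimation + validation) only, and stored; test data are transformed with
stored states, never refit. Mapping states are refit per cross-validation
fold for the same reason. Missing cells are imputed with the training
median (interval) or mode (categorical); rows with a missing class label
are dropped at load time.

## Feature weighting and selection (I-RELIEF)

Predictors are weighted by iterative RELIEF: each sample receives
probabilistic nearest-hit and nearest-miss distributions with weights
`exp(-d / kernel_width)` under the current weighted Manhattan distance, and
the new weight vector is the positive part of the average per-feature
margin (expected miss distance minus expected hit distance), renormalized
to unit Euclidean norm; iterate to a fixed point. Features at or above the
mean weight are retained by default (`select_by_weight()`); the cut is
data-driven because no fixed retained-feature count generalizes across
cohorts. On class-independent features the sign-truncated update ends on a
random sign pattern, so single runs may concentrate weight arbitrarily —
absence of *systematic* dominance (seed-averaged weights near uniform) is
the meaningful null property, and is what the test suite asserts.

## Majority-class selective sampling (PSS)

Imbalance is reduced by keeping only the majority-class samples near the
minority class, where the decision boundary must be resolved. Each majority
sample's Euclidean distance to its nearest minority sample is computed; the
sample is kept iff that distance is at or below the global
`distance_quantile` (default 0.75) of those distances. Chunked processing
exists solely for memory/parallelism; because the keep rule is a global
quantile, results are chunk- and worker-count independent. If the rule
would push the majority below the minority count, the nearest excluded
samples are added back in distance order — the class ratio moves toward 1:1
and never beyond. PSS is applied to the **estimation partition only**: the
ridge solve benefits from a rebalanced fitting set, while the validation
partition keeps its natural imbalance so that unit fitness is measured on
data shaped like the deployment population.

## The network

Each network unit regresses the class on a pair of inputs through a
nonlinear basis of `Nn = 7` functions with 14 tunable coefficients:

$$X = \begin{pmatrix}
a_1 \\ a_2 (1+x_i)^{a_3} \\ a_4 x_j^{a_5} \\ a_6 \sin(a_7 x_i + a_8 x_j) \\
a_9\, x_i \odot (1+x_j)^{a_{10}} \\ a_{11}\log_2(1+(1+x_i)^{a_{12}}) \\
a_{13}\log_2(1+(1+x_j)^{a_{14}}) \end{pmatrix}$$

Amplitudes are bounded in [-5, 5] and exponents in [0.1, 3], which makes
every basis entry finite for inputs in [0,1] (no `0^negative`). The basis
list is deliberately a closed, quotable set of seven rows; further rows are
an extension point, not a default.

For fixed coefficients the unit weights solve a ridge problem in closed
form, $W = (XX^\top + \lambda I)^{-1} X B$ with $\lambda = 0.1$ and the 0/1
class labels as $B$ — the unique global minimum of the penalized
least-squares objective. The 14 basis coefficients are tuned by a bounded,
seeded particle swarm (global-best topology, constriction-style defaults
0.729/1.49/1.49, swarm 20, 10 evaluation sweeps): each particle proposes
coefficients, $W$ is solved on the estimation partition, and the particle
is scored on the **validation** partition by the imbalance-aware fitness

$$\mathrm{fitness} = \tfrac{1}{3}(Se + Sp + Pr)$$

at the 0.5 score cutoff. This convex-inner/stochastic-outer split is the
core design: the swarm only searches the 14-dimensional coefficient box,
never the weight space, so a few sweeps suffice.

Layers grow classically: all feature pairs of a layer are trained (capped
at `max_pairs_per_layer = 200`, enumerating pairs of the most important
features first), the best `ceiling(0.7 * P)` units survive
(selection pressure 0.7; fitness ties broken by lower pair index), and
their clipped-to-[0,1] outputs become the next layer's features — outputs
only, original predictors are not carried forward. The layer count is
`1 + round(log2(Ni + Nd))` (round-half-to-even, so the rule is
deterministic), where `Ni` and `Nd` count the interval and indicator
predictors. The best unit of the final layer is the output unit. If a layer
is left with a single surviving unit before the target depth, the network
stops deepening there — that unit is already the layer's best, and raising
an error would make any two-predictor cohort unfittable; only a first layer
with fewer than two features is an error.

# Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `lambda` | 0.1 | ridge penalty | stabilizes the 7×7 solve; scale set by the [0,1] bases |
| `selection_pressure` | 0.7 | fraction of units kept | balances diversity against layer growth |
| `cutoff` | 0.5 | score threshold | scores approximate a 0/1 target |
| `n_layers` | auto | layers | input-count rule above |
| `max_pairs_per_layer` | 200 | pairs | bounds the quadratic pair growth at desk scale |
| `val_fraction` | 0.2 | of training | the 10%-of-total validation share of a 40/10/50 design |
| PSO swarm / sweeps | 20 / 10 | — | the inner RLS solve makes long swarms unnecessary |
| PSO inertia, c1, c2 | 0.729, 1.49, 1.49 | — | constriction-stable standard values |
| I-RELIEF `kernel_width` | 2 | L1 distance units | mild locality on [0,1] predictors |
| I-RELIEF `max_iter`, `tol` | 50, 1e-4 | — | fixed-point iteration budget |
| PSS `distance_quantile` | 0.75 | quantile | retains the boundary-proximal three quarters |

The PSO budget above is the network's inner tuning budget. As a
general-purpose optimizer `pso_maximize()` converges on smooth problems
with a standard budget; the convergence test uses 50 sweeps, which is an
optimizer property check, not a change to the classifier's configuration.

# Evaluation machinery

`compute_metrics()` reports the full two-class battery: Se, Sp, Acc, Pr,
F1, false alarm (= 1 - Sp), FDR (= 1 - Pr), likelihood ratios, diagnostic
odds ratio DOR = LR+/LR-, discriminant power
DP = (sqrt(3)/pi) * log10(DOR), MCC and Cohen's kappa. Two conventions
deserve note. First, `AUC` here is the balanced-accuracy form
`(Se + Sp)/2` evaluated at the fixed cutoff — the form used in the
diagnostic battery this package mirrors; a rank-based ROC area is available
separately as `roc_auc()` to avoid ambiguity. Second, DP uses base-10
logarithms with the sqrt(3)/pi factor: that convention reproduces the
worked value DP ≈ 1.3 at DOR ≈ 252, which pins down the log base. Zero
cells yield `Inf` likelihood ratios / DOR rather than a Haldane-corrected
finite value, and a degenerate margin flags MCC as `NaN`.

The clinical reliability gate requires, jointly and inclusively:
Se ≥ 0.80, Sp ≥ 0.95, Pr ≥ 0.95 and DOR ≥ 100.

Classifiers are compared by McNemar's test on the discordant decisions
against the gold standard. The continuity-corrected chi-square statistic is
always reported; the p-value uses the exact binomial when the discordant
count is below 25 and the chi-square tail otherwise (forceable either way
— published analyses are not always explicit about which variant produced
a p-value, so both routes are first-class).

`evaluate_holdout()` (40/10/50 by default) and `evaluate_cv()` (4 folds,
60/15/25 within each fold) drive a classifier factory through
class-stratified, seed-reproducible splits; stratified allocation uses a
largest-remainder rule whose ties are resolved toward the partition with
the largest cross-stratum shortfall, so overall partition sizes track the
requested fractions as closely as integer counts allow.

# The synthetic cohort generator

`dyslipidemia_spec()` transcribes the class-conditional structure of a 725-
subject pediatric dyslipidemia case-control cohort: prevalence 0.4234,
genotype frequencies of eleven lipid-pathway polymorphisms, categorical
exposure frequencies (family histories, abdominal obesity, BMI category,
physical activity, birth weight, sex, region) and interval means ± SD (age,
blood pressures, fasting blood sugar), each given separately for cases and
controls. Percentages that fail to sum to 100 due to printed rounding are
renormalized with a logged note. `generate_cohort()` draws the class from
Bernoulli(prevalence) and every feature independently from its
class-conditional distribution.

What this emulates — and what it does not: the generator reproduces the
published *marginal* class-conditional distributions only. Features are
conditionally independent given the class; real cohorts carry linkage
disequilibrium between SNPs and correlations among anthropometric variables
(e.g. BMI with waist-to-height ratio) that are not represented. Passing
tests on generated cohorts therefore demonstrates that the pipeline
recovers marginal class signal and behaves correctly as software; it does
not certify performance on data with real dependence structure, and no
generated-cohort result should be read as a reproduction of the original
study's classification accuracy.

`generate_separable()` provides controlled benchmarks: informative interval
features shifted by two standard deviations between classes, exact
integer class counts at a requested imbalance ratio, pure-noise features,
and an optional XOR pair — two features individually uninformative
(univariate rank AUC ≈ 0.5) whose parity determines the class. The XOR
construction is the canonical probe that pairwise units capture
interactions no univariate screen can see.

# Numerical choices and degenerate inputs

* Heterozygote genotype order is canonicalized by sorting the two
  nucleotides alphabetically ("TG" and "GT" merge into "GT"), giving
  deterministic category identity.
* Unit scores are clipped to [0,1] before reuse as next-layer inputs, so
  the basis preconditions hold recursively.
* Constant interval features (zero MAD) abort `fit_robust_z()` with the
  feature named; the pipeline-level `predictor_map()` drops them with a
  warning instead, keeping the fit total.
* Equal-fitness units are ordered by lower (i, j) pair index; equal RELIEF
  weights by lower column index — all ties deterministic.
* Every stochastic component (splits, swarm, sampling, generators) takes an
  explicit seed argument and restores the caller's RNG state; nothing
  depends on or mutates global RNG state.
* Model persistence is plain JSON at full double precision; a reloaded
  model reproduces scores to within write-format echo (~1e-14).

# Problem sizes

The test suite and the acceptance script run at the scales the methods are
specified at: XOR recovery on n = 400 cohorts over three seeds, I-RELIEF
discrimination at n = 200, the Hardy–Weinberg type-I error on 1000
simulated cohorts of n = 500 at allele frequency 0.3, and the full
pipeline-determinism checks on cohorts of 160–300 subjects. These sizes
were chosen as the package's own test design and keep the complete suite
in the tens of seconds on one CPU.

# Known limitations

* The generator's conditional-independence assumption (above) is the main
  gap between synthetic and real cohorts; a dependence-aware generator
  (e.g. Gaussian-copula interval blocks) would be the natural extension.
* The reported `AUC` is threshold-bound; use `roc_auc()` for
  threshold-free comparisons.
* Baseline learners in `run_compare()` are standard library
  implementations configured to conventional settings (pruned `rpart`
  tree, 10-unit `nnet`, grid-tuned RBF `e1071::svm`, `glm` logit); the
  comparison harness makes qualitative contrasts, not reproductions of any
  published baseline table.
* GMDH layer fitness tends to be non-decreasing across layers but is not
  guaranteed to be; the suite tracks it as a statistical property.
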