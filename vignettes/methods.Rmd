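---
title: "Active learning for drug-target interaction prediction: models, simulation design and stopping rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active learning for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Screening every drug against every target is rarely affordable. Given a
panel of N drugs and M targets, the outcome of each assay is binary — the
drug affects the target (+1) or it does not (-1) — and the goal is to
learn the full N x M interaction matrix **Y** from as few assays as
possible. `dtal` implements the two ingredients this requires:

1. an *active learner* that, given the experiments performed so far,
   predicts the rest of the matrix and chooses which experiments to run
   next; and
2. a *stopping rule* that estimates how accurate the current model is
   without access to the unmeasured ground truth, so experimentation can
   end once the model is good enough.

The state of an experimentation campaign is the ternary *experimental
matrix* **X**: +1/-1 where the assay has been run, 0 where it has not.
The zero entries form the unlabeled pool.

## The learner: kernelized Bayesian matrix factorization

Prior knowledge enters through two similarity kernels: a drug kernel
`Kd` (N x N, e.g. chemical-structure similarity) and a target kernel
`Kt` (M x M, e.g. normalised sequence-alignment similarity). KBMF
projects both kernels into a shared R-dimensional subspace through
transformation matrices `A_d` (N x R) and `A_t` (M x R) and scores every
pair with the product of the projected kernels,

$$\mathbf{F} = \left((\mathbf{A_d})^{T}\mathbf{K_d}\right)^{T}
              \left((\mathbf{A_t})^{T}\mathbf{K_t}\right),$$

predicting an interaction wherever `F > 0`. Because predictions for a
drug only require its kernel row, the model generalises to drugs (or
targets) with no measured experiments at all — the property the drug-wise
protocol below exploits.

Inference is mean-field variational Bayes for the semi-supervised binary
model: observed entries of `F` follow truncated normal distributions
forced to the correct side of a margin, the projected factors
`G = A' K` carry Gaussian noise, and the entries of the transformation
matrices have zero-mean Gaussian priors with entry-wise gamma
hyperpriors. Only observed entries enter the likelihood; each drug's
(target's) factor posterior uses exactly its observed entries, which is
what makes the model usable from the first handful of assays.

Tunable parameters, their defaults, and why:

* `R = 20` (dimensionless): subspace dimension; 20 is the value
  established as a good operating point for the public drug-target
  benchmarks. The simulation studies in this package use `R = 10`
  because their 50 x 50 systems are smaller than those benchmarks.
* `iterations = 200`: the variational updates typically converge in
  about 200 sweeps; `tol` (relative change of the prediction matrix,
  default off) enables early stopping, and warm starts across
  active-learning rounds make later fits converge in far fewer sweeps.
* `margin = 1`, `alpha_lambda = beta_lambda = 1`, `sigma_g = 0.1`:
  the reference values for this inference scheme; all configurable.
* Initialization: `A` matrices start at `0.01 * N(0, 1)` (seeded).
  Symmetric all-zero starts would lock the factors; any small random
  scale works and the scale itself is absorbed within a few sweeps.

The posterior probability of an interaction is the sigmoid
`P = 1 / (1 + exp(-F))`, computed in an overflow-safe form; `|F|` acts
as the model's confidence.

## The active-learning loop

Each round fits KBMF to the revealed labels, predicts the whole matrix,
records the true accuracy on the remaining pool, and queries the next
batch (`run_trace()`). Initialization reveals one full random column plus
one random experiment per drug, so every drug and at least one target
start with data; a diversity variant balances initial experiments over
k-means clusters of the two kernels. Query strategies:

* **Uncertainty sampling** (`select_batch_entries()`): binary entropy
  `U = -(P log P + (1-P) log(1-P))` (natural log; only the ordering
  matters), greedy top-K over the pool, ties broken by a seeded draw.
* **Drug-wise sampling** (`select_batch_drugs()`): drugs ranked by mean
  entropy over their unlabeled entries; the top 1% of drugs are fully
  measured. This mirrors campaigns where plates are organised per drug.
* **Random sampling**: the baseline every strategy must beat.

## Simulated systems

Calibrating a stopping rule needs many fully-known systems, which real
screens cannot provide. Two scalar statistics parameterise the simulated
interaction matrices:

* *responsiveness* `r`: the fraction of +1 entries;
* *uniqueness* `u`: (distinct rows + distinct columns) / (N + M) — how
  independent the drug and target profiles are, i.e. how hard the matrix
  is to complete.

`generate_interaction_matrix()` builds a core pattern matrix with
`round(u * (N + M))` distinct row/column prototypes, tiles it to N x M,
and then runs a greedy local search (core-cell flips and prototype-size
moves, each accepted only if it preserves prototype distinctness) until
the realised responsiveness is within `tol = 0.02` of target. This
constructive-plus-repair design reaches the grid interior reliably and
fails loudly — naming the achieved (u, r) — at infeasible corners
(e.g. `r = 0` forces the constant matrix and hence the minimum
uniqueness `2 / (N + M)`).

"Perfect" kernels are derived from the ground truth itself: Gaussian
similarities of drug profiles (rows) and target profiles (columns), with
the bandwidth set by the median heuristic (median positive pairwise
distance). Kernel unreliability is emulated by forcing a fraction
(0, 5 or 10%) of off-diagonal symmetric pairs to 1 — maximal similarity,
i.e. the entry carries no information — followed by eigenvalue clipping
and rescaling back to unit diagonal (`regularize_psd()`), since
corruption can make a kernel indefinite. Corruption counts unordered
off-diagonal pairs so the unit diagonal is never touched.

The default calibration grid (`build_grid()`) crosses
u, r in {0.05, ..., 0.95} with noise in {0, 0.05, 0.10} at 50 x 50.
The test suite and the acceptance script use a reduced
5 x 5 x 2 sub-grid (u, r in {0.1, 0.3, 0.5, 0.7, 0.9}, noise in
{0, 0.05}), batch size 10% of entries, `R = 10`, and early-stopped,
warm-started fits (60-sweep cap, `tol = 1e-3`), giving traces of about
11 rounds; these sizes are the package's own choice of simulation
granularity and keep a full calibration run in minutes on one core.

**What the generator does not emulate.** Duplicated profiles are *exact*
duplicates (uniqueness counts exact distinctness), prototype blocks make
the structure low-rank, and kernels are derived from the truth rather
than from chemistry or sequences. Real screens have near-duplicates,
measurement noise on the labels themselves, and kernels whose errors are
structured, not uniform. Passing the simulated checks therefore
demonstrates the machinery end-to-end under controlled difficulty — not
performance on any particular real screen.

## Predicting accuracy and deciding when to stop

Thirteen features summarise each time-point (observed and predicted
responsiveness by row/column, stability of consecutive posterior grids,
precision of the previous round's positive predictions on newly measured
entries, and min/max/mean per-drug and per-target observation counts,
normalised by the opposite dimension). Quadratic structure is added by
appending the square roots of all pairwise products, giving 91
predictors in [0, 1]. Interpretation choices where the feature
definitions were open: posterior *probabilities* (not labels) are
compared across rounds, because late-run label flips are too rare to
carry signal; the "new observations" feature uses as denominator the
newly measured entries that the previous round predicted interacting,
and is 0 when that set is empty; count features are divided by the
opposite dimension to land in [0, 1]; normalization constants are
computed once on the training pool and stored in the predictor.

The regression target is the *adjusted accuracy* — true pool accuracy
minus the fraction of experiments performed — which removes the
mechanical improvement that comes from the pool shrinking. The model is
a lasso (L1-penalised least squares, coordinate descent over a ~100
point lambda grid via `glmnet`), with the penalty chosen by 11-fold
cross-validation grouped at the level of whole trajectories, so a run
never informs its own fold; 11 folds rather than 10 leaves slightly more
training data per fold. Adding the fraction performed back, and clipping
to [0, 1], turns the output into an accuracy prediction.

Calibration (`cv_calibrate()`) asks, per predicted-accuracy bin (width
0.05, half-open, ties counted as fulfilled): how often is the true
accuracy at least the predicted one? On the reduced grid this exceedance
probability is low in the mid-range (early, data-poor rounds
over-predict), rises through the 0.8-0.9 bins, and the predictions
become trustworthy lower estimates in the region where stopping is
actually contemplated — which motivates the default stopping rule:
terminate when the predicted accuracy reaches 0.9 (`pa_stop()`).

Two classical criteria are implemented for comparison: overall
uncertainty (mean pool entropy, in nats) and minimum expected error
(mean `1 - max(P, 1 - P)`), each with fixed thresholds or an "adapted"
variant. The adaptation scheme here is our reading of threshold
relaxation by label consistency: once more than 99% of pool labels are
unchanged between consecutive rounds, the criterion's current value is
accepted, i.e. the run stops at the first label-consistent round.
Stopping rules are scored by `delta_ave()`: the mean absolute distance,
in percentage points of experiments, from the *best stopping time* (the
first round attaining the maximum true accuracy).

## The drug-wise protocol

`run_drugwise_protocol()` evaluates generalisation to unseen drugs:
5-fold cross-validation over drugs (80% train / 20% test), drug-wise
uncertainty batches of 1% of drugs within the training set, stopping
when the predicted accuracy *on the training pool* reaches 0.9, and
rank-based AUC (mid-rank ties) of the prediction scores on the held-out
drugs. The pre-clustering baseline (`precluster_baseline()`) instead
picks a representative training set up front: k-means on the drug
kernel, cluster count by AIC under a spherical-Gaussian likelihood
(k scanned over 2..ceiling(sqrt(N))), drugs drawn round-robin across
clusters nearest-centroid first.

## When does uncertainty sampling help?

A finding worth stating plainly, because it shapes what the synthetic
checks can show. On simulated systems the advantage of uncertainty
sampling over random sampling depends strongly on uniqueness. At high
uniqueness (u = 0.9; few duplicated profiles — the regime the public
drug-target benchmarks resemble) uncertainty sampling dominates. At
mid-to-low uniqueness it can *lose* to random sampling: uniqueness
below 1 means exactly duplicated drug/target profiles, duplicated
entries have identical prediction scores and hence identical
uncertainty, and the greedy batch spends many queries on mutually
redundant entries while random sampling spreads over the distinct
prototype blocks. This is a property of greedy entropy batches on
block-structured ground truth with self-derived kernels, not of the
implementation; the paired-trace tests in the suite compute both
regimes. A batch-diversity correction would mitigate it but is
deliberately out of scope — plain greedy selection is the strategy this
package sets out to study.

## Numerical choices and degenerate inputs

* Sigmoid and truncated-normal moments are computed in log space
  (`plogis`, log-scale Mills ratio), safe for `|F| > 700`.
* `F = 0` predicts -1 (the "else" branch of the sign rule); posterior
  probabilities are clamped strictly inside (0, 1).
* All-zero experimental matrices, non-square kernels, kernels with NAs,
  batch sizes exceeding the pool, and single-class held-out sets raise
  immediate, named errors.
* Kernels are symmetrized on read by averaging with their transpose; a
  non-unit diagonal warns rather than errors, since kernel scale is
  absorbed by the transformation matrices.
* The trace runner always leaves at least one pool entry, so recorded
  accuracy is never computed on an empty set.
* Every stochastic step (initialization, fits, tie-breaks, fold
  assignment, corruption) flows from explicit integer seeds; identical
  seeds give bit-identical traces, predictors and pipeline outputs.

## Limitations

* The accuracy predictor is calibrated on simulated traces; transferring
  it to a real campaign assumes the campaign's (u, r, kernel-quality)
  regime is covered by the training grid.
* Exceedance calibration is reported per bin; sparsely occupied bins
  (very low or very high predictions) carry wide uncertainty and are
  reported with their counts, never imputed.
* The learner ships with a single factorization backend; the loop is
  model-agnostic (any scorer that yields probabilities could drive it),
  but no other backend is provided.
* Kernel construction from chemistry or sequences is out of scope; the
  package consumes kernels, it does not compute them.
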