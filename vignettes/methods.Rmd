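---
title: "Models and methods behind maeopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind maeopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maeopt)
```

maeopt models microwave-assisted extraction of phenolics (Folin–Ciocalteu
reducing capacity, FCRC) and flavonoids (AlCl₃ complexation) from plant
press residue as a function of four process factors, and optimizes the two
responses jointly. This vignette explains the statistical models, the
algorithmic choices that were genuinely open, and what the tests do and do
not establish.

## The design and its coding

A four-factor Box–Behnken design places runs at the midpoints of the edges
of the factor hypercube: for each of the six factor pairs, four runs with
that pair at (±1, ±1) and the other factors at their centre, plus centre
replicates — N = 2k(k−1) + C₀ = 27 runs for k = 4, C₀ = 3. Coding is linear
in the midpoint and half-range of each factor's `[low, high]` interval.
Nothing in the data dictates this coding, but it is the only affine choice
that sends the three design levels to −1/0/+1, and the shipped dataset's
printed predictions are reproduced exactly under it. `generate_bbd()` emits
a canonical deterministic order (factor pairs lexicographically, centre
runs last); the packaged dataset instead preserves its original run order
through `run_id`, which is why its patterns are data, not re-derived.

## The response-surface model

Each response's 27 run means are fitted by ordinary least squares to the
full second-order polynomial in coded factors — intercept, four linear,
four pure quadratic and six interaction terms (p = 15). Three choices merit
a note:

* **Run means, unweighted.** The replicate-level observations are not
  available, only means ± sd. Weighting by 1/sd² would change the printed
  coefficient table; unweighted fitting of the means reproduces it to the
  printed precision, which identifies it as the procedure actually used.
  The sds are retained for lack-of-fit testing and for calibrating the
  synthetic generator.
* **RMSE uses residual degrees of freedom** (n − p = 12), i.e. the root of
  the residual variance estimate, matching standard design-of-experiments
  software output (6.94 and 1.60 for the two responses here).
* **Pure error from centre replicates only.** The three centre runs are
  the only replicated point, so the lack-of-fit partition has 2 pure-error
  and 10 lack-of-fit degrees of freedom. Coefficient p-values are
  two-sided t tests on 12 df, without multiplicity correction, as is
  conventional for DoE coefficient tables.

The *full* 15-term model is canonical throughout the package. Reduced
displays that drop non-significant terms are common in publications, but
only the full model reproduces the dataset's printed prediction column, so
pruning is deliberately not implemented.

One data quirk is preserved rather than repaired: the packaged prediction
column disagrees with the refit model at a single entry (run 22, FCRC,
printed 322.46 vs modelled 325.47 — a digit transposition). The loader
documents it; tests exclude exactly that cell.

## KNN surrogate

The k-nearest-neighbour regressor is deliberately built from scratch,
because the metric variety is the point: Euclidean, Chebyshev, Minkowski
(exponent a tunable in [1, 10]), Mahalanobis, cosine, correlation,
Spearman, Hamming, Jaccard, cityblock and standardized Euclidean, each
under equal, 1/d and 1/d² neighbour weighting. Conventions the literature
leaves open were fixed as follows (all are what the major numerical
environments do):

* Jaccard on real vectors: unequal, not-both-zero coordinates over
  not-both-zero coordinates; 0/0 → 0. Hamming: proportion of exactly
  unequal coordinates. On the ±1/0-coded design these behave like
  set-overlap measures, which is why they can excel on this geometry.
* Cosine/correlation/Spearman distances are 1 − similarity with degenerate
  vectors (zero or constant) assigned distance 1; Spearman uses
  average-rank ties.
* Mahalanobis and standardized-Euclidean statistics come from the
  *training* inputs only, with a 1e−8 ridge when the covariance is
  near-singular.
* Neighbour ties break by (distance, training index), stable and
  documented; predictions are otherwise row-order invariant.
* Zero-distance rule: if any selected neighbour coincides with the query,
  the prediction is the unweighted mean of the coinciding targets. This is
  what makes training-set evaluation under inverse weighting exact — and
  why near-perfect training correlations in tuned-KNN tables should be
  read as a property of the estimator, not evidence of generalization.

Normalization to [−1, 1] is fitted on the **entire** dataset before the
70/30 split, reproducing the stated preprocessing order of the original
workflow. This leaks the feature ranges (not the targets) across the
split; with a bounded designed experiment the min/max are design constants
anyway, so the leakage is nil in practice.

## Dragonfly optimizers

The source study names the dragonfly algorithm but gives no update
equations, so the implementation follows the canonical formulation:
per-agent separation, alignment and cohesion within a neighbourhood radius
that grows linearly over iterations, attraction to the best-so-far (food),
repulsion from the worst-so-far (enemy), step
ΔX ← sS + aA + cC + fF + eE + wΔX with the separation/alignment/cohesion
weights drawn as 2·U(0,1)·c_t (c_t decaying from 0.1 to 0 by mid-run),
food weight 2·U(0,1), enemy weight c_t, and inertia w annealed 0.9 → 0.4.
Agents with no neighbours and no food in radius take a Mantegna Lévy
flight (exponent 1.5). Steps are clamped to a tenth of the box per
iteration; positions clip to bounds with the offending step component
zeroed. All of these are exposed through `da_config()` rather than
hard-coded.

The multi-objective variant keeps a bounded archive of mutually
non-dominated solutions. Crowding uses a fixed hypercube segmentation (10
segments per objective over the archive's objective bounding box); food is
drawn by roulette from sparse cells (weight 1/count), the enemy from
crowded ones (weight count), and truncation at capacity removes from the
most crowded cells. Capacity (100), segment count and the weight schedule
are explicit package defaults — the original study reports none of them.

Hyperparameter tuning encodes the mixed space (metric index, weighting
index, k, Minkowski exponent) continuously and rounds discrete dimensions
at evaluation time. The search budget default — 100 iterations × 30
agents — is the budget the original tuning reports. A baseline
configuration (Euclidean, equal weights, k = 3) is injected into the
initial swarm so the tuner can never return something worse than a sane
default. The tuner's objective is validation RMSE; its evaluation log is
returned so the reported optimum is auditable as the argmin of the log.

## Desirability composition

The study validates a "desirability-based" optimum but never defines the
function, so the package makes the standard choice: Derringer maximize-type
scores d = ((y − L)/(T − L))^s clipped to [0, 1], combined by geometric
mean (`desirability()`, `overall_desirability()`). For the *search* inside
`optimize_rsm()` the upper clip is dropped: with targets at achievable
values, clipping floods the top of the composite surface with exact ties
(every point where all responses exceed their targets scores 1) and the
argmax degenerates to an arbitrary plateau point. The unsaturated score
preserves the ordering below the targets and is strictly discriminating
above them; anchors default to the observed minimum (L) and the model's
maximum grid prediction (T) per response, s = 1. Under these defaults the
optimum lands at maximum power and maximum irradiation time with ethanol
at its low bound — the same corner the study's validated optima occupy.
The search itself is a dense grid (11 points per axis by default, 14,641
evaluations for k = 4 — exhaustive at negligible cost) refined by
L-BFGS-B from the best grid point.

The Pareto-archive compromise over KNN surrogates maximizes the **sum** of
the predicted responses across archive members, because the study's
validation table reports summed-response totals; the surrogates used here
are trained on all 27 runs (the split exists only to give the tuner a
validation signal, and a deployed predictor should use all data).

## The synthetic generator

`simulate_bbd_dataset()` draws replicate observations as
truth + N(0, σ²) around a known second-order surface and records run
means and sds, mimicking the triplicate protocol (n = 3 per run). Noise is
homoscedastic: the real data's per-run sds vary (≈0.3–4.7 units for the
phenolic response) but no variance model is available, so a single
configurable σ is the minimal assumption; σ = 2 is used in the recovery
studies as a mid-range value. What the generator does **not** emulate:
run-to-run heteroscedasticity, instrument drift or blocking, non-quadratic
curvature, and any correlation between the two responses' errors. Tests
passing on synthetic data therefore establish the estimator's correctness
under the model's own assumptions, not robustness to their violation.

## Problem sizes and numerical choices

The test-suite simulations use 50 seeded replicates for the
coverage/recovery properties (the analysis script runs 200); recovery
coverage bands are widened accordingly (90–100% around the nominal 95%).
Optimizer checks use the study's own budget (100 × 30) on the 4-D sphere
and reduced budgets (tens of iterations, 15–25 agents) for archive and
tuning properties, which keeps the whole suite around a minute on one CPU.
Degenerate inputs are errors, not silent fixes: constant features in the
normalizer, k below 3 in the design builder, non-finite objective values,
L ≥ T desirability anchors, and empty validation splits all signal
immediately.

## Known limitations

* The original 70/30 membership and RNG are unknown, so the published
  tuning-table R/RMSE values are qualitative references; the package
  reproduces the *procedure* and its invariants, not those four numbers.
* The published table of fitted coefficients for the flavonoid response
  contains several non-significant entries that no OLS variant reproduces
  (the significant entries and the full prediction column all agree); the
  packaged fixture keeps the printed values, and tests anchor only on the
  reproducible ones.
* Swarm optimizers carry no convergence guarantee; seeded determinism and
  the baseline-injection guarantee are the only hard claims made.
* Predictions outside the coded box are extrapolation and are not guarded
  beyond the documentation.
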