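---
title: "Geoadditive ordinal regression: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geoadditive ordinal regression: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`spatord` fits structured additive regressions for an ordered categorical
outcome (child birth-size categories are the motivating case) and for its
binary detrimental-outcome reduction.  The cumulative (proportional-odds)
model arises from a latent utility `Z = w + eps` with logistic error:
`y = j` exactly when `theta_{j-1} < Z <= theta_j`, so

    P(y <= j | w) = F(theta_j - w),      F(x) = 1 / (1 + exp(-x)),

with strictly increasing thresholds and a predictor shared by all
categories,

    w = v' gamma + sum_k f_k(x_k) + f_str(s) + f_unstr(s).

Assumptions worth stating explicitly:

* **Proportional odds.** One `w` for all categories — covariates shift
  the whole latent distribution, they do not act category-specifically.
  No partial-proportional extension is offered.
* **Logistic error.** Cumulative logits, hence coefficient exponentials
  are (cumulative) odds ratios.
* **Sign convention.** Positive coefficients move mass toward *higher*
  categories.  The binary model is parameterized as
  `P(y = 1) = F(gamma_0 + w)` with `y = 1` the detrimental (low-weight)
  outcome, so the *same* protective covariate carries a positive
  cumulative coefficient and a negative binary one.  This mirroring is
  enforced by a dedicated simulation audit in the test suite.
* **Conditional independence.** Given covariates and region effects,
  outcomes are independent; survey design (clustering, weights) is out of
  scope.

### Term types

* **Fixed effects** use ±1/0 effect coding: one column per non-reference
  level, +1 at the level's rows, −1 at the reference's rows.  Relative to
  treatment dummies this halves two-level contrasts and shifts the
  intercept's meaning to a level-average; coefficients are *not*
  comparable across the two codings.
* **P-splines**: B-spline basis of degree `d` (default cubic) on
  equidistant knots over the covariate range (extended by `d` knots per
  side), with a difference penalty of default order 2.  Defaults — 20
  inner knots, cubic, second-order — are the conventional choices of the
  structured-additive-regression software family; with REML smoothing the
  results are insensitive to the knot count once it is generous.
* **Structured spatial effect**: one coefficient per region, penalized by
  the graph Laplacian `K = diag(degree) − adjacency` of the supplied
  adjacency graph — the intrinsic-CAR / MRF penalty, whose quadratic form
  is the sum of squared neighbour differences.
* **Unstructured spatial effect**: i.i.d. region effects with an identity
  (ridge) penalty, capturing heterogeneity that does not follow the map.

### Identifiability

Smooth terms are centered to sum to zero over the observed data by an
exact reparameterization (`center_constraint`); the structured spatial
term is centered per connected component automatically, because the
Laplacian's null space (the per-component constants) is removed in the
mixed-model split.  The binary model keeps a free intercept; the
cumulative model has none — the level is absorbed by the thresholds.

The unstructured term is *not* constrained: its ridge penalty is a proper
prior that shrinks the region mean toward zero on its own, and an exact
sum-to-zero constraint on an i.i.d. effect is nonstandard.  This is a
deliberate deviation from a symmetric "center both" design; in practice
the estimated unstructured means are numerically tiny.

Isolated regions (degree 0) span their own Laplacian null space, so their
structured effect is exactly zero and all their variation is carried by
the unstructured term.

## Estimation

Each penalized term with basis `B` and penalty `K` is split spectrally
(`reparameterize`): eigenvectors with zero eigenvalue form an unpenalized
fixed-effect block, and the rest are whitened (`Z = B V+ L+^{-1/2}`) so
the implied penalty is the identity and each smoothing parameter becomes
a variance component `tau^2`.

**Inner loop.** At fixed variances, coefficients maximize the penalized
log-likelihood by Fisher scoring.  The binary model uses standard IWLS.
The cumulative model uses the full multicategorical machinery: per
observation the score and expected information of the `K−1` cutpoint
predictors `a_j = theta_j − w` form a tridiagonal weight matrix, which is
chained onto the threshold and coefficient parameters; the normal
equations are assembled per term.  Thresholds are carried as
`(theta_1, log-increments)`, so ordering is structural and can never be
violated mid-iteration.  Every step is step-halved until the penalized
log-likelihood does not decrease, making the inner iteration monotone.
Convergence: relative coefficient change below `1e-8` (cap 100
iterations).

**Outer loop.** Variances are updated by the working-model REML (Schall)
iteration: with `C = (H + S)^{-1}` the posterior covariance and `b_j` the
whitened block coefficients,

    tau_j^2  <-  ||b_j||^2 / (q_j − tr(C_jj) / tau_j^2),

clamped below at `1e-8` (a floored component has effectively collapsed to
its null space).  This update shares its fixed point with Fisher scoring
of the REML criterion on the log-variances but is bounded and cannot
overshoot into negative variances — which is why it was chosen over a raw
Fisher-scoring step.  Its drawback is linear convergence, with rate close
to one when the structured and unstructured spatial variances compete for
the same signal (their sum is well identified, their split only weakly).
The implementation therefore applies per-component Aitken extrapolation
on the log scale: the linear rate is estimated from consecutive raw
updates and the iterate jumps toward the fixed point, with each jump
capped at 1 log-unit.  Convergence is declared on the *raw* steps —
relative change of all coefficients and log-variances below `1e-6`, cap
200 outer iterations — so acceleration can speed the path but not fake
convergence.  The `converged` flag is honest: a capped run reports
`FALSE` and still returns the last iterate.

**Uncertainty.** "95% intervals" are empirical-Bayes Wald intervals from
the penalized information matrix `C` — the penalized-likelihood analogue
of the credible intervals reported by the software family this design
follows.  Threshold intervals are delta-method transforms from the
log-increment parameterization.  These intervals condition on the
estimated `tau^2`; variance-component uncertainty is not propagated (a
known source of mild undercoverage for the smooth bands, not for fixed
effects at the sample sizes tested).

**Model summaries.** Effective degrees of freedom are the hat-matrix
trace `tr((H+S)^{-1} H)`; `AIC = −2LL + 2 df`, `BIC = −2LL + df log n`.
The GCV criterion reported alongside is *deviance-based*,
`(−2LL/n) / (1 − df/n)^2`.  The source tables this mirrors never define
their GCV; this formula reproduces the one printed value that is checkable
from its own row (−2LL, df, and the classified-record count), and is
exposed as an interpretation, not a fact about the original software.

## Numerical choices

* Knot vectors place the boundary knots *exactly* at the range endpoints
  (`seq(..., length.out = )`), avoiding spurious out-of-range errors at
  the data maximum; evaluation outside the knot range is a hard error, no
  silent extrapolation.
* Probabilities inside likelihood weights are floored at `1e-10` (and at
  `1e-300` inside logs); IWLS weights at `1e-10`.
* Near-singular normal equations fall back to a relative `1e-8` ridge.
* Complete separation in the binary model is detected by working linear
  predictors exceeding ±20 (fitted probabilities within `2e-9` of 0/1);
  the model is refitted with a `1e-4` ridge on the unpenalized block and
  the event is logged and warned.
* Degenerate inputs are rejected with named errors: empty outcome
  categories, non-increasing thresholds, undeclared factor levels,
  asymmetric adjacency files, region labels absent from the graph.
* All stochastic operations take an explicit integer seed and restore the
  caller's RNG state; identical configuration and seed yield byte-identical
  pipeline artifacts.

## The synthetic world

The restricted survey microdata cannot be shipped, so the generator
*states* a world with the model's exact structure and defaults fixed once:

* `n = 5000` children on a **synthetic** 37-region graph (6×6 rook lattice
  plus one appended node — the node count of a 36-states-plus-capital map,
  not its true adjacency).
* thresholds `(-1.9, 0.1, 1.6)` — the magnitudes of published
  intercept-only cumulative fits of four-way birth-size frequencies;
* three continuous covariates on realistic maternal ranges with a U-shaped
  age effect (minimum at 32 years), a sigmoid BMI effect and a weak linear
  weight effect, each with amplitude a few tenths on the logit scale;
* three two-level categorical effects of |gamma| 0.08–0.18 (effect-coded),
  matching the order of magnitude of reported fixed effects in birth-size
  analyses;
* spatial variances `tau2_str = 0.3`, `tau2_unstr = 0.05`: moderate,
  structured-dominated heterogeneity typical of disease-mapping
  applications.

These defaults were chosen once, before any acceptance measurement, and
are not tuned.  What a green recovery test establishes: with data *from
the model*, the pipeline recovers fixed effects with near-nominal interval
coverage, ranks regions by their combined spatial effect with median
Spearman correlation above 0.8, and locates the U-shape minimum within a
sixth of the covariate range.  What it does not establish: robustness to
proportional-odds violations, informative survey design, measurement
error in self-reported sizes, or real adjacency topology — none of which
the generator emulates.

## Outcome recoding

Weight-based recoding follows the model definitions: binary `1` iff
`<= 2500 g`; ordinal cuts `< 2.5`, `[2.5, 3.2)`, `[3.2, 4.0)`,
`>= 4.0` kg.  Two published inconsistencies are resolved in code and
flagged here rather than hidden: the descriptive binning ("large =
3.3–4.0") conflicts with the model cut (`>= 3.2`), and a weight of
exactly 2.5 kg is *low* under the binary rule but *average* under the
ordinal rule.  The implementation follows the model definitions verbatim;
unclassifiable records are dropped with a logged count.

## Known limitations

* The structured/unstructured variance split is weakly identified; only
  the total spatial effect should be interpreted quantitatively (the
  `total` option of `classify_regions`).  The REML path may place the
  same total differently between the two components across replicates.
* No multiplicity correction across regions or coefficients — matching
  the reporting tradition this follows; the null-calibration test
  documents the resulting familywise behaviour (about the nominal 5% of
  regions flagged under a true null, fewer in practice because of
  shrinkage).
* Intervals are empirical-Bayes Wald intervals; fully Bayesian MCMC
  uncertainty is out of scope.
* `fit_cumulative` assumes every category is observed; sparse extreme
  categories should be merged upstream.
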