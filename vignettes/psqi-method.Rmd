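---
title: "Multi-task GP water-quality mapping and the PSQI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task GP water-quality mapping and the PSQI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A regional water-quality survey measures tens of chemical parameters
(pH, major ions, nutrients, trace metals) at scattered sampling points, while
regulators and decision systems need two things everywhere in between:
(a) predicted concentrations with honest uncertainty, and (b) a single
interpretable statement of whether the water is likely to comply with the
sanitary standards.  `psqigeo` answers both with one joint model: a
multi-task Gaussian process (GP) over all parameters at once, and a
**Probabilistic Substance Quality Index (PSQI)** — the weighted probability
that each regulated parameter lies within its admissible range — evaluated
from the GP's predictive distribution over a uniform spatial grid.

## The model

Let $\mathbf{x} \in [0,1]^2$ be scaled projected coordinates and
$\mathbf{z}(\mathbf{x}) \in \mathbb{R}^M$ the warped measurements (next
section).  The model is

$$\mathbf{z}(\mathbf{x}) = \boldsymbol\mu(\mathbf{x}) + \mathbf{f}(\mathbf{x})
  + \boldsymbol\varepsilon,\qquad
  \operatorname{Cov}\!\left[f_k(\mathbf{x}), f_l(\mathbf{x}')\right]
  = K^f_{kl}\, k^x(\mathbf{x}-\mathbf{x}'),\qquad
  \boldsymbol\varepsilon \sim \mathcal N(0, D),$$

so the joint covariance over all $N$ locations and $M$ tasks is the Kronecker
sum $\Sigma = K^f \otimes K^x + D \otimes I_N$ with $D$ diagonal per-task
noise.  Its three ingredients:

* **Spatial kernel** $k^x$: a spectral mixture of $Q$ components,
  $k^x(\tau) = \sum_q w_q \prod_{p=1}^2
  \exp(-2\pi^2\tau_p^2 v_p^{(q)})\cos(2\pi\tau_p\mu_p^{(q)})$.
  Its spectral density is a Gaussian mixture, so it approximates any
  stationary kernel as $Q$ grows; $Q$ is the complexity dial and is chosen by
  cross-validation, not by hand-crafting kernels.
* **Task covariance** $K^f = BB^\top + \operatorname{diag}(\mathbf v)$ with
  $B$ an $M\times r$ matrix: a low-rank-plus-diagonal parameterization that
  both regularizes and cheapens the $M\times M$ inter-parameter covariance.
  After training, $\operatorname{cov2cor}(K^f)$ *is* the inter-parameter
  correlation analysis.
* **Trend** $\boldsymbol\mu(\mathbf{x})$: a full quadratic polynomial in the
  two coordinates, one coefficient vector per task, absorbing regional trends
  the stationary kernel cannot express.

Hyper-parameters maximize the exact log marginal likelihood of the flattened
$NM$-vector.  Predictions use the standard conditional-Gaussian formulas with
cross-covariance $K^f \otimes k^x_*$; the default implementation whitens by
the task noise and eigendecomposes the two Kronecker factors
($O(N^3 + M^3)$ instead of $O(N^3M^3)$), and a naive dense route over the
flattened system is kept for small problems as the internal cross-check —
the two agree to machine precision in the test suite.

## Coordinate and measurement normalization

Coordinates are projected from geographic degrees to metric UTM (Krüger
series on WGS84; the zone defaults to that of the data centroid, zone 37N
around 37°E) and min-max scaled to the unit square.  The scaler is fitted on
the training samples only and reused for every prediction grid, because the
fitted length-scales are expressed in these scaled units.

Concentrations are non-negative and pH lives in $[0,14]$, while a GP is
Gaussian with infinite support, so measurements are **warped**: per
parameter, (1) fix an upper limit at $10\cdot\max\{y^{\max}, b^U\}$ (the
observed maximum or the regulatory upper bound, decadically inflated so new
data cannot overflow) — except for hard physical domains such as pH, which
use the domain itself; (2) min-max scale to $[0,1]$; (3) replace exact zeros
(detection-limit values sitting on the lower limit) by $10^{-10}$; (4) apply
the standard-normal inverse CDF; (5) min-max scale again with constants from
the training data.  The composite map is strictly increasing and invertible,
so interval probabilities transfer exactly between the two spaces.  At
prediction time, values at or beyond the scaling endpoints are clamped
inward by a relative $10^{-12}$ before the inverse CDF, which diverges at 0
and 1.

## Validation and model selection

Candidates over a grid of $(Q, r)$ are compared by 5 random 80/20
train/test splits ("5 random splits" is read as independent resamples; a
disjoint k-fold mode exists behind `mode = "kfold"`).  Everything
data-dependent — scaler, warp, GP — is refitted on each training fold.
Scores are per-parameter $R^2 = 1 - \mathrm{MSE}/\operatorname{Var}$ in the
**original** measurement space (predictive means are inverse-warped first;
the non-linear warp makes warped- and original-space $R^2$ differ).
Parameters whose split-averaged $R^2$ is negative under *every* candidate
are masked out; the candidate with the highest mean over kept parameters and
splits wins, ties towards smaller $Q$ then smaller $r$.  Zero-variance test
cells yield `NA` and are excluded from averages rather than counted as 0.

## PSQI and confidence

At a location the model yields an $M$-variate Gaussian
$\hat p(\mathbf z \mid \mathbf x_*)$ in warped space.  For regulated
parameter $i$ with warped bounds $[b_i^L, b_i^U]$,

$$\hat p_i(\mathbf x_*) = \int_{-\infty}^{\infty}\!\cdots\!
  \int_{b_i^L}^{b_i^U}\!\cdots\!\int_{-\infty}^{\infty}
  \hat p(\mathbf z\mid\mathbf x_*)\,\mathrm d\mathbf z,
\qquad
\mathrm{PSQI}(\mathbf x_*) = \sum_i w_i\, \hat p_i(\mathbf x_*).$$

Because all other coordinates are integrated over the whole real line, the
rectangle integral collapses *exactly* to a difference of two univariate
Gaussian CDF values of the $i$-th marginal — the closed form used
throughout (numerical integration of the full multivariate density survives
only as an independent oracle in the tests, where the two agree below
$10^{-6}$).  Consequences worth knowing: PSQI is free of integration error
at any number of map points, is independent of the inter-parameter
correlations, and is monotone under widening of any bound.

The **confidence** companion repeats the computation with the mean vector
replaced by the warped-interval midpoints: it is high exactly when the
predictive spread is small against the admissible range, regardless of where
the mean sits, and coincides with PSQI when the predictive mean is already
at the midpoints.

Weights are $w_i \propto \exp(\max(R^2_i, 0))$ over the regulated
parameters (softmax of clamped cross-validated scores), so poorly modelled
parameters contribute less; ad-hoc importances can multiply and renormalize
them.  Parameters with non-positive $R^2$ are additionally *replaced* by
their warped-space dataset mean and variance with zero inter-parameter
covariance (the model has no predictive value for them, the constant does),
making their marginal contribution location-independent.

Two open points were decided as follows and are exposed as flags:

* **Integration space.** Bounds are mapped into warped space and integrated
  against the warped-space Gaussian — the probability-preserving choice,
  since the predictive distribution is Gaussian only there.  A naive
  original-space mode (`space = "original"`, delta-method standard
  deviation) exists for comparison.
* **One-sided standards.** "Not above the limit" rules get lower bound 0:
  concentrations are physically non-negative and the PSQI rectangle stays
  finite.  The printed Fe range "0.3–1" is read strictly (upper bound 0.3)
  with the permissive reading (1) available as an override.

## The synthetic generator

`generate_dataset()` emulates the structure of a regional survey so every
stage is testable without field data: uniformly scattered locations in a
~20 km box (with 15% replicated sites carrying independent noise), latent
fields drawn from the *exact* model family (Q = 1 Gaussian-envelope kernel,
length-scale 0.2 scaled units, rank-2 task covariance with correlations
between −0.46 and 0.77, quadratic trend), pushed through a fixed monotone
warp into bounded units shaped like a drinking-water table (two-sided pH,
one-sided nitrate- and iron-like bounds, one unregulated parameter), plus
8% relative measurement noise and detection-limit zeros (5%/10% of the two
trace-like columns, injected by thresholding the lowest quantile — the
model treats zeros as a warping nuisance, not as a censoring likelihood, so
the generator does the same).  Defaults (N = 200, M = 4) are the reference
study conditions of the test suite and were chosen as a realistic
small-survey regime; the generator does not attempt to replicate any real
region's spatial covariance or full marginals, so passing tests demonstrate
method correctness and recoverability in a well-specified world, not
performance on real surveys (where warp misspecification, non-stationarity
and sampling bias will lower accuracy, as they do for the poorly modelled
trace metals in real deployments).

## Numerical choices

* **Optimizer**: Adam, learning rate 0.1, 300 iterations, over unconstrained
  raw parameters; positive quantities via softplus.  Gradients are analytic
  (block-structured trace identities on the dense representation) and are
  checked against finite differences to $10^{-4}$ relative.
* **Length-scale box**: the over-fitting guard constrains each component's
  envelope length-scale $\ell^{(q)}_p = 1/(2\pi\sqrt{v^{(q)}_p})$ to
  $[0.1, 100]$ scaled units.  The mapping raw → $\ell$ is a scaled logistic
  rather than a hard clamp, keeping the gradient exact everywhere.
* **Initialization** (seeded): weights split the total warped variance over
  components; spectral means start at random *low* frequencies (uniform up
  to one cycle per unit domain — an initialization at the far higher Nyquist
  frequency of the sample spacing plants oscillatory components that lock
  onto noise rather than signal); length-scales start at 0.3; the trend at
  per-task means; noise at 10% of per-task variances.
* **Multi-start**: the spectral-mixture likelihood is multi-modal, and poor
  local optima distort the fitted task covariance while also scoring a
  visibly worse marginal likelihood — so the likelihood itself arbitrates.
  The final bundle fit uses 3 random restarts and keeps the best final
  likelihood; the throwaway cross-validation fits use 1.
* **Jitter**: on Cholesky failure, $10^{-6}$ is added to the diagonal,
  escalating tenfold up to $10^{-2}$ before erroring.
* **Ties** in model selection break towards smaller $Q$, then smaller $r$
  (prefer the simpler model).
* **Degenerate inputs**: constant measurement columns, all-identical
  coordinates, all-parameters-masked selections, and sub-minimal test folds
  are explicit errors, not silent results.

## Problem sizes

The suite runs the full loop at N = 200 samples, M = 4 parameters, a
6-candidate $(Q, r)$ grid and 5 splits — sizes chosen so the whole benchmark
is a few minutes on one core while leaving each training fold (160 points)
large enough for stable hyper-parameter estimates.  Map products in the
tests use up to a few hundred grid points; the prediction path itself
reuses one factorization across arbitrarily many points, so production grids
of $10^5$+ points differ only in wall time.

## Known limitations

* The warp is a fixed data-driven transform; there is no learned warping,
  and exact zeros are re-mapped to near-zero values rather than modelled as
  censored observations.
* The spatial kernel is stationary; strong non-stationarity must be absorbed
  by the quadratic trend or it will inflate the noise estimates.
* One regulation table per run; no unit conversions are attempted (bounds
  are stored verbatim in the table's units).
* Cross-validated $R^2$ on replicated-measurement datasets is mildly
  optimistic when replicates of one site straddle the train/test split.
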