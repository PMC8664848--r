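# psqigeo

Joint geo-spatial modelling of multi-parameter water chemistry and a
regulation-driven **Probabilistic Substance Quality Index (PSQI)**.

Regional water surveys measure many interdependent properties (pH, major
ions, nutrients, trace metals) at scattered points, while users need
predictions with uncertainty everywhere in between and a single, regulation-
anchored statement of quality. `psqigeo` is for hydrologists, environmental
monitoring teams and decision-support builders who have a samples table, a
table of admissible bounds, and a region to map.

## The model

All M parameters are modelled together by a multi-task Gaussian process over
the two scaled map coordinates:

- joint covariance `Σ = K^f ⊗ K^x + D ⊗ I_N`, with a **spectral mixture
  kernel** `k^x(τ) = Σ_q w_q Π_p exp(−2π²τ_p²v_p^(q)) cos(2πτ_p μ_p^(q))`
  (complexity set by the mixture size Q, chosen by cross-validation), a
  **low-rank task covariance** `K^f = B Bᵀ + diag(v)` (rank r, also chosen
  by cross-validation) and diagonal per-task noise `D`;
- a quadratic polynomial trend per parameter;
- bounded measurements are first **warped** into an unbounded space
  (min-max scaling by `10·max{y_max, b_U}`, zero replacement at 1e-10,
  standard-normal inverse CDF, second min-max), where the GP assumptions
  hold; the warp is monotone, so interval probabilities transfer exactly.

At any location the model yields an M-variate Gaussian; for each regulated
parameter the probability of lying inside its admissible range
`[b_L, b_U]` (all other parameters integrated out) reduces in closed form to
a difference of two Gaussian CDF values, and

```
PSQI(x) = Σ_i w_i · P( b_i^L ≤ z_i ≤ b_i^U | x ),   w_i ∝ exp(max(R²_i, 0))
```

with weights from cross-validated per-parameter R² scores. A companion
**confidence** metric recentres the predictive mean at the bound midpoints,
separating "bad water, certain" from "good water, uncertain". Packaged
default bounds reproduce the SanPiN 1.2.3685-21 drinking-water table (21
parameters, 18 regulated); any CSV/YAML bounds table can be supplied.

## Worked example

Simulate a four-parameter survey (the packaged generator draws from the
exact model family over a ~20 km box), search (Q, r) by 5×80/20
cross-validation, fit the winner and map PSQI:

```r
library(psqigeo)

rb <- recovery_benchmark(synth_config(), q_grid = 1:3, r_grid = c(2, 3))
rb
#> Synthetic recovery benchmark
#>   selected model: Q=2, r=2 (mean held-out R2 0.762 over pH, NO3, Fe, K)
#>   task-correlation MAE vs truth: 0.084
#>   PSQI vs fraction-in-bounds Pearson r: 0.864
```

Read: the held-out predictions explain 76% of the original-unit variance of
the kept parameters; the inter-parameter correlation matrix read off the
optimized `K^f` is within 0.08 (mean absolute) of the generating truth; and
PSQI at the sampling locations correlates 0.86 with the measured fraction of
parameters inside their bounds — the model-free sanity check of the index.

Mapping over a grid:

```r
model <- rb$model
g <- make_grid(bbox_utm = c(model$scaler$min_xy[1], model$scaler$min_xy[2],
                            model$scaler$min_xy[1] + 1000,
                            model$scaler$min_xy[2] + 1000),
               spacing = 100, scaler = model$scaler)
nrow(g)                      # 121 points: 11 x 11 inclusive 100 m lattice
map <- predict_map(model, g)
range(map$psqi)              # per-point index in [0, 1]
write_map_geojson(map, "map.geojson")
```

The same stages run from the shell via the thin wrapper
`inst/cli/psqi-geo.R` (`simulate | validate | fit | map`), driven by one
YAML config or flags (`--seed`, `--bbox`, `--spacing`, `--q-grid`, ...);
every command writes a manifest from which its artifacts are reproducible.

## Layout

- `R/` — standards, projection/scaling, warping, multi-task GP core,
  cross-validation and selection, PSQI, grids/maps, synthetic generator,
  pipeline
- `inst/extdata/sanpin_1_2_3685_21.csv` — packaged regulatory bounds
- `vignettes/psqi-method.Rmd` — models, assumptions, design decisions
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (brute-force dense GP, tensor-product quadrature, Monte Carlo)
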