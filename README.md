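# pcmlink

True-score equating of polytomous scales with the partial credit model
(PCM), for settings where the same respondents answered two multi-item
scales measuring (nearly) the same construct — the *common person design*
typical of instrument-crosswalk and data-harmonization work in health
research.

## What it does

Given an `N x (I_X + I_Y)` matrix of three-category responses, `pcmlink`

1. fits each scale separately and checks the Rasch assumptions (item
   infit/outfit, threshold ordering, local dependency, residual-based
   dimensionality),
2. fits a two-dimensional PCM whose latent correlation ρ̂ quantifies how
   similar the two constructs really are,
3. concurrently calibrates all items with one unidimensional PCM, placing
   all thresholds δ̂ on a common metric,
4. anchors each scale on those thresholds and tabulates the ability
   estimate for every raw score, and
5. builds the bidirectional **concordance table**: each raw score on one
   scale is linked to the raw score on the other scale whose anchored
   ability is nearest (`argmin |θ̂_X − θ̂_Y|`, ties toward the lower
   score).

Estimation is marginal maximum likelihood (EM over a quadrature grid,
slopes fixed at 1, latent mean 0, latent variance — and for two dimensions
the correlation — estimated). The core model function is `pcm()`, which
returns a classed object with `print()`, `summary()`, `coef()`,
`logLik()` and `simulate()` methods.

Transformation quality is measured against the identity baseline (same
number on both scales) with NRMSE — RMSE as a fraction of the score range
— percent bias, and the MSE = variance + bias² decomposition. A
Monte-Carlo study runner (`settings_grid()`, `run_repetition()`,
`run_setting()`, `run_grid()`, `score_error_curves()`) regenerates the
full 432-setting factorial experiment varying construct similarity
(ρ ∈ {0.25, 0.5, 0.75, 1}), ability dispersion (σ_θ ∈ {0.5, 1, 2}),
difficulty shift (Δ ∈ {0, 1, 2} logits), targeting
(σ_δ pairs (1,1), (2,2), (1,2)), sample size and scale length.

## Worked example

```r
library(pcmlink)
g <- settings_grid()
s <- g[g$setting_id == "I10_N0500_r0.75_t1.0_d1_s1-1", ]  # rho=.75, 1-logit shift
dat <- simulate_equating_data(s, seed = 42)
eq <- equate_scales(dat$responses, diagnostics = TRUE)
print(eq)
```

```
True-score equating (common person design)
Partial credit model (1-dimensional, slopes fixed at 1)
  500 persons, 20 items, log-likelihood -8114.57 (converged, 17 EM iterations)
  latent SD: 0.854

Transformation precision on the calibration sample:
 direction     method nrmse percent_bias rmse   bias variance
      XtoY true_score 0.158       -1.167 3.17 -0.078     10.0
      YtoX true_score 0.173        0.644 3.46  0.074     12.0
      XtoY   identity 0.293      -71.835 5.85 -4.800     11.2
      YtoX   identity 0.293       41.805 5.85  4.800     11.2

Construct similarity (2-D latent correlation): 0.762
```

The 2-D fit recovers the generating similarity (ρ̂ = 0.762 vs ρ_sim =
0.75). With a 1-logit difficulty shift the identity baseline misses by
almost 30% of the score range and carries massive bias, while the
true-score transformation stays near 16% NRMSE with negligible bias —
equating absorbs the difficulty difference. The first concordance rows
show the same thing concretely: a raw score of 4 read on the (easier)
Scale X corresponds to a 1 on the (harder) Scale Y, whereas a 4 read on
Scale Y corresponds to a 9 on Scale X:

```r
head(as.data.frame(eq$concordance), 8)
#   raw_score equated_x equated_y
#           0         3         0
#           1         4         0
#           2         6         0
#           3         7         0
#           4         9         1
#           5        10         1
#           6        11         2
#           7        12         3
```

`write_concordance(eq$concordance, "crosswalk.csv", eq$tables)` exports
the table in the conventional three-column layout. For real data in two
CSV files, `crosswalk("capacity.csv", "performance.csv", id_column = "id")`
runs the whole workflow including the diagnostic report.

## Package layout

- `R/settings.R`, `R/simulate.R` — settings grid, seed derivation, and the
  bivariate-normal / PCM response generator
- `R/pcm-fit.R`, `src/pcm_em.cpp` — MML-EM estimation (1-D core in C++,
  2-D in R)
- `R/theta.R` — TCC inversion, EAP tables, anchored person estimates
- `R/equating.R` — concurrent calibration, concordance, transformations
- `R/diagnostics.R` — the Rasch fit battery and report
- `R/metrics.R` — NRMSE, percent bias, MSE decomposition
- `R/study.R` — repetition/setting/grid runners and summaries

The methods vignette (`vignettes/true-score-equating.Rmd`) documents the
model, the estimator choices and the simulation design in detail.
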