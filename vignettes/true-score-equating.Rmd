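---
title: "True-score equating of polytomous scales with the partial credit model"
author: "pcmlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{True-score equating of polytomous scales with the partial credit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmlink)
```

## The problem

Health and patient-reported-outcome research routinely measures the same
construct with different multi-item scales. When every respondent has
answered both scales (a *common person design*), the scales can be equated:
a lookup table — a *concordance table* or crosswalk — links each raw score
on Scale X to the most equivalent raw score on Scale Y. `pcmlink`
implements the true-score route to that table under the partial credit
model (PCM), together with a Monte-Carlo study of how construct
similarity, targeting and difficulty shifts degrade the transformation.

## Model

Items are polytomous with three ordered categories \(x \in \{0, 1, 2\}\).
Under the slope-1 PCM the probability that person \(n\) with ability
\(\theta_n\) scores \(x\) on item \(i\) with step thresholds
\(\delta_{i1}, \delta_{i2}\) is

\[
\Pr(X_{ni} = x) =
 \frac{\exp \sum_{h \le x} (\theta_n - \delta_{ih})}
      {\sum_{x'} \exp \sum_{h \le x'} (\theta_n - \delta_{ih})},
\]

with the empty sum equal to zero. The raw score of a scale is a sufficient
statistic for \(\theta\), and the expected raw score as a function of
\(\theta\) — the test characteristic curve (TCC) — is strictly increasing.

`pcm()` estimates the thresholds by marginal maximum likelihood: an EM
algorithm integrates \(\theta\) out over a rectangle-rule grid of 61 nodes
spanning \(\pm 6\) latent standard deviations (31 nodes per dimension for
the two-dimensional model). Identification follows the Rasch convention:
latent mean(s) fixed at zero, slopes fixed at one, latent variance(s) — and
for two dimensions the latent correlation — estimated from the posterior
second moments. Convergence is declared when the relative log-likelihood
change falls below `1e-6` (at most 500 iterations); the trace is stored so
the monotonicity of the EM can be asserted. The E-step and the per-item
Newton updates of the one-dimensional fit are implemented in C++ because a
simulation study runs thousands of fits.

## The equating workflow

`equate_scales()` (and, for CSV input, `crosswalk()`) runs the four
canonical steps:

* **A — separate calibrations.** Each scale is fitted on its own and passed
  through the diagnostic battery (below). A two-dimensional fit provides
  the latent correlation \(\hat\rho\) between the scales — the
  construct-similarity statistic that best predicts equating quality.
* **B — concurrent calibration.** One unidimensional PCM over all items of
  both scales, *regardless* of the true dimensionality, places all
  thresholds \(\hat\delta_{XY}\) on a common metric.
* **C — anchoring.** With thresholds fixed at \(\hat\delta_{XY}\), each
  raw score of each scale receives an ability estimate, tabulated by
  `build_score_theta_tables()`.
* **D — concordance.** For each raw score on one scale the equated score on
  the other is the raw score whose anchored ability is nearest in absolute
  distance; exact ties break toward the lower raw score. The table is
  written in the conventional three-column crosswalk layout by
  `write_concordance()`.

The naive baseline, `identity_transform()`, declares a score on X equal to
the same number on Y (clipped when ranges differ). Transformation quality
is summarized by `nrmse()` (RMSE divided by the theoretical score range
\(0\) to \(2I\)), `percent_bias()`
(\(\sum(R - \hat R) / \sum R \times 100\); below 10% in absolute value is
conventionally negligible), and `mse_decomposition()`
(\(\mathrm{MSE} = \mathrm{Var} + \mathrm{Bias}^2\), where the variance term
is the variance of the transformation error so the identity holds exactly).

### Which person estimate anchors the table?

Step C admits more than one person-parameter estimator, and the choice is
consequential, so it deserves its own paragraph. The package offers two
routes in `score_theta_table()`:

* `"eap"` (default): the posterior mean of \(\theta\) given the raw score,
  with the concurrent fit's latent distribution as prior. This is what the
  standard MML IRT software reports for anchored person parameters.
* `"tcc"`: maximum likelihood by TCC inversion (`score_to_theta()`),
  bracketed bisection to a `1e-8` tolerance. The extreme raw scores, whose
  ML estimate is infinite, are solved after the conventional 0.3
  score-point adjustment, which is what gives published concordance tables
  finite equated values in the extreme rows.

The two routes agree closely when the concurrent model is well specified.
They part ways when the two scales measure clearly distinct constructs:
fitting a unidimensional PCM to two-dimensional data compresses the
between-scale metric (the fitted latent SD and the separation between the
scales' threshold distributions both shrink — this is the maximum of the
misspecified marginal likelihood, not an estimation defect, as a profile
likelihood over the latent SD confirms). Under ML/TCC tables that
compression propagates into a systematic over-prediction when transforming
from the easier to the harder scale; the EAP prior pulls both tables back
toward the common center and largely cancels it. In our simulations of the
least favourable cell (\(\rho = 0.25\), \(\sigma_\theta = 2\),
\(\Delta = 2\), 10-item scales, \(N = 500\)) the percent-bias quartiles are
roughly \((-16, +8)\) under TCC tables but \((-9, +5)\) under EAP tables —
only the latter consistent with percent bias remaining in the negligible
band. EAP is therefore the default; `method = "tcc"` remains available and
`score_to_theta()` is the building block for either route.

## Diagnostics

The battery reported by `fit_report()` mirrors what applied equating
studies tabulate at Steps A and C:

* **Item fit** — infit (information-weighted) and outfit (unweighted) mean
  squares of standardized residuals, computed at the anchored person
  estimates; the default acceptance band is \([0.7, 1.3]\).
* **Threshold ordering** — \(\hat\delta_{i1} < \hat\delta_{i2}\).
* **Local dependency (LID)** — the largest absolute off-diagonal
  correlation between item residuals; a pair standing 0.2 or more above the
  mean residual correlation is flagged.
* **Dimensionality** — items are split by the sign of their loading on the
  first principal component of the residual correlation matrix, each
  person's ability is estimated from both subsets, and the percentage of
  persons whose two estimates differ significantly (per-person t statistic,
  \(\alpha = 0.05\)) is reported; materially more than 5% indicates a
  second dimension.
* **Targeting** — means and SDs of item locations and person estimates.

These residual-based conventions are standard Rasch practice; the exact
cut-offs are documented defaults, not estimated quantities.

## The simulation study

`settings_grid()` enumerates the \(4 \times 3 \times 3 \times 3 \times 2
\times 2 = 432\) data-generating conditions:

| factor | levels | meaning |
|---|---|---|
| `rho_sim` | 0.25, 0.5, 0.75, 1 | latent correlation between the scales' dimensions (construct similarity; 1 = unidimensional) |
| `sigma_theta` | 0.5, 1, 2 | ability SD (logits), identical for both dimensions |
| `shift` | 0, 1, 2 | difficulty difference \(\Delta_{XY}\): location means \(\mp\Delta/2\) |
| `sigma_delta` | (1,1), (2,2), (1,2) | item-location SD per scale (targeting) |
| `n_persons` | 500, 1000 | sample size |
| `n_items_per_scale` | 10, 20 | scale length |

For each setting, `draw_abilities()` samples \(\theta\) pairs from a
bivariate normal with covariance \(\rho_{sim}\sigma_\theta^2\) (the
dispersion parameter is interpreted as a standard deviation — the stated
correlation identity \(\rho = \sigma_{XY}/\sigma_X\sigma_Y\) forces this
reading); `draw_item_parameters()` draws item locations per scale and
places the two thresholds at \(\pm d\) around each location with
\(d \sim N(0.7, 0.15)\), floored at 0.05 logits so thresholds are always
ordered (untruncated draws below zero are astronomically rare, but the
floor makes the ordering a guarantee rather than an expectation);
`simulate_responses()` draws categories from the PCM at each person's
ability on the item's own dimension. Item banks are re-drawn in every
repetition, so the repetition-level variation includes bank-sampling
variation, and one master seed spawns per-setting, per-repetition child
seeds (`child_seed()`) so any single repetition can be reproduced in
isolation.

`run_repetition()` executes generate → concurrent calibration → anchored
tables → concordance → transform (both directions, true-score and
identity) → precision metrics. Replicates where the fit does not converge
or some item category is never observed are re-drawn with a derived seed
(at most 5 attempts, counted in the output). When redraws are exhausted —
in the most poorly targeted settings (\(\sigma_\theta = 0.5\) with
\(\sigma_{\delta} = 2\)) an unobserved top category is the norm rather than
the exception — the replicate is analysed anyway: the affected thresholds
sit at the estimation boundary (\(\pm 12\) logits), where the category
carries negligible probability mass and the TCC over the observed score
range is essentially unaffected. Discarding such replicates wholesale
would systematically bias those settings' summaries toward their easier
draws.

`run_setting()`/`run_grid()` aggregate repetitions into long-format
results; `summarize_results()` reports Q1/median/Q3/min/max per setting,
direction, method and metric with the linear-interpolation quantile rule
(`stats::quantile`, type 7). `score_error_curves()` profiles the mean
transformation error (± one SD) along the raw-score continuum, where the
loss of precision toward the extremes of the scale is visible.

## What the generator does and does not emulate

The generator reproduces the designed statistical structure exactly:
bivariate-normal abilities, normal item locations with symmetric difficulty
shifts, equidistant thresholds. Real scales deviate from this in ways the
study deliberately holds fixed: categories can be unevenly used, thresholds
disordered, items locally dependent or differentially functioning, and
ability distributions skewed or floor/ceiling-compressed. Passing tests
therefore certify the behaviour of the equating machinery under clean,
well-behaved items — an intentionally optimal setting — not performance on
any particular field instrument. Scale-specific diagnostics
(`fit_report()`) are the tool for judging real data before trusting a
crosswalk.

Two further points. First, with narrow ability dispersion
(\(\sigma_\theta = 0.5\)) and long scales, multidimensional generation is
reported in the literature to be delicate (realized inter-scale
correlations can drift above their nominal input); this package's generator
is exact in that respect — the realized correlation converges to
`rho_sim` — so quantities at nominally low similarity and narrow dispersion
can be mildly less favourable here than in studies whose generators
drifted. Second, all precision statistics use the theoretical score range
\(0\) to \(2I\), not the observed range.

## Numerical choices

* Quadrature: 61 nodes (1-D) / \(31 \times 31\) (2-D) on \(\pm 6\) latent
  SDs, rectangle rule with normal weights; the grid rescales with the
  current SD estimate.
* Per-item M-step: bounded two-parameter Newton ascent (step cap 2 logits,
  threshold cap \(\pm 12\)); degenerate information falls back to a scaled
  gradient step.
* TCC inversion: vectorized bisection on an expandable bracket (start
  \([-10, 10]\)), 60 halvings — far below the stated `1e-8` tolerance.
* EAP tables: 201-node posterior grid.
* Ties in the concordance argmin break toward the lower raw score —
  deterministic and conservative.
* Transformed scores are integers (table lookup, no interpolation), which
  is how published crosswalk tables are used.
* The 2-D latent correlation is capped at \(\pm 0.999\) so the grid
  weights stay defined at the unidimensional boundary.

## Problem sizes used in the tests

The packaged acceptance checks rerun the study at reduced replication
counts chosen to keep the whole suite desk-scale: 20–30 repetitions per
setting for the band checks (smoke grid of 12 settings; the 27
perfect-similarity settings per scale length; the 9 worst-case settings)
and 100 repetitions for the two single-setting direction-asymmetry checks.
Quantile estimates from 20–100 repetitions carry Monte-Carlo error
relative to a 500-repetition study; the checks state explicit allowances
(±0.02 NRMSE, ±1.5 percent-bias points) for exactly that reduced
replication.

## Known limitations

* Three response categories and slope-1 items only; no DIF, no
  within-scale multidimensionality, no missing-data handling beyond
  complete-row analysis (`collapse_categories()` is provided for items
  whose top category is unobserved in real data).
* Only the common person design: no anchor-item (NEAT) equating, no
  observed-score (equipercentile/kernel) methods, no testlet
  co-calibration.
* The concurrent calibration is deliberately unidimensional even when the
  data are not — that is the method under study, and its metric
  compression under low similarity is part of the findings, not a bug to
  be corrected.

## A worked run

```{r example, eval = FALSE}
g <- settings_grid()
s <- g[g$setting_id == "I10_N0500_r0.75_t1.0_d1_s1-1", ]
dat <- simulate_equating_data(s, seed = 42)
eq <- equate_scales(dat$responses, diagnostics = TRUE)
print(eq)
eq$concordance
summarize_results(run_setting(s, n_reps = 30, master_seed = 42)$results)
```
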