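---
title: "From stem maps to a spatial zero-inflated binomial mortality model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stem maps to a spatial zero-inflated binomial mortality model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During the 2012–2016 Californian hot drought, the western pine beetle (WPB,
*Dendroctonus brevicomis*) killed ponderosa pine (*Pinus ponderosa*) at
unprecedented rates across the Sierra Nevada. Whether a given stand loses
trees depends on broad-scale water stress — summarised by climatic water
deficit (CWD) — interacting with local forest structure: how many of the
trees are hosts, how large they are, and how densely they grow. `pipomort`
implements the full analysis chain needed to study these cross-scale
interactions from individual-tree survey data (for example drone-derived
stem maps): plot-level structure metrics and detector benchmarking, crown
spectral classification, height and allometric calibration, aggregation to
20 × 20 m grid cells, and a zero-inflated binomial regression with per-site
spatial Gaussian processes.

## The model

For cell $i$ in site $j$, with $n_i$ host trials (live ponderosa plus all
dead trees, which are assumed to be ponderosa) and $y_{i,j}$ dead trees:

$$
y_{i,j} \sim \begin{cases} 0 & \text{with probability } p \\
\mathrm{Binom}(n_i, \pi_i) & \text{with probability } 1 - p \end{cases}
$$

$$
\begin{aligned}
\mathrm{logit}(\pi_i) = \beta_0
 &+ \beta_1 X_{cwd,j} + \beta_2 X_{propHost,i} + \beta_3 X_{height,i}
  + \beta_4 X_{density,i} + \beta_5 X_{BA,i} \\
 &+ \beta_6 X_{cwd,j} X_{height,i} + \beta_7 X_{cwd,j} X_{propHost,i}
  + \beta_8 X_{cwd,j} X_{density,i} + \beta_9 X_{cwd,j} X_{BA,i} \\
 &+ \beta_{10} X_{propHost,i} X_{height,i}
  + \beta_{11} X_{propHost,i} X_{density,i}
  + \beta_{12} X_{height,i} X_{BA,i} \\
 &+ \beta_{13} X_{cwd,j} X_{propHost,i} X_{height,i}
  + \mathcal{GP}_j(x_i, y_i)
\end{aligned}
$$

The five base covariates are centred and scaled pooled across sites before
interaction columns are formed (products of standardized columns, not
re-centred — so interaction columns generally have nonzero mean, which is
intentional and matches how the design is usually built in this
literature). $p$ is a single global zero-inflation probability describing
an independent, unmodelled process that leaves a cell with no dead trees.
$\mathcal{GP}_j$ is a separate *exact* Gaussian process per site over raw
(unscaled) cell-centroid coordinates in metres, with the exponentiated
quadratic kernel

$$k(d) = \sigma_j^2 \exp\!\left(-\frac{d^2}{2\ell_j^2}\right),$$

evaluated with the full dense covariance matrix and a Cholesky
factorization (no low-rank approximation). We use an isotropic kernel (one
length-scale per site); the coordinate pair enters jointly, and nothing in
the data sets considered here suggested direction-dependent ranges.

### Priors

The priors are weakly regularizing stand-ins chosen to be proper and
diffuse relative to the scale of log-odds effects:

* intercept $\beta_0 \sim t_3(0, 2.5)$;
* slopes $\beta_1, \ldots, \beta_{13} \sim \mathcal{N}(0, 5)$;
* $p \sim \mathrm{Uniform}(0, 1)$;
* GP amplitudes $\sigma_j \sim$ half-$t_3(0, 2.5)$;
* GP length-scales $\ell_j \sim$ inverse-gamma with shape 3 and scale set
  per site so the prior mode is one quarter of the site's coordinate range
  (the prior adapts to each site's physical extent, keeping mass away from
  length-scales far below the cell size or far beyond the site).

Sensitivity: halving or doubling the slope prior sd (2.5 vs 10) moves the
desk-scale posterior medians of the well-identified coefficients (CWD, host
proportion, CWD × height) by much less than their posterior spread, because
with hundreds of cells and thousands of host trials the likelihood
dominates. The prior matters more for the GP hyperparameters, which are
weakly identified per site; that is why the length-scale prior is
deliberately informative about scale.

### Sampler

Fitting uses Markov chain Monte Carlo written for this model: Hamiltonian
Monte Carlo with analytic gradients over the coefficients, the logit of
$p$, the log GP amplitudes, and *whitened* GP values ($f_j = \sigma_j L_j
v_j$ with $v_j \sim \mathcal{N}(0, I)$ and $L_j$ the Cholesky factor of the
unit-variance kernel), combined with a random-walk Metropolis step for each
site's log length-scale conditional on the whitened values. Step size is
tuned by dual averaging to an 0.8 acceptance target, a diagonal mass matrix
is estimated from a middle warmup window, the number of leapfrog steps is
jittered uniformly over 16–32 per iteration, and the length-scale proposal
scale is adapted toward a 0.4 acceptance rate during warmup. Moving the
length-scales by Metropolis rather than HMC avoids kernel-matrix
derivatives at the cost of slower mixing for $\ell_j$ — an accepted
trade-off since the scientific targets are the $\beta$ coefficients.

Convergence gates follow the usual reporting practice for this model
family: split-$\widehat{R} < 1.1$ for every monitored parameter and bulk
and tail effective sample sizes above 100 times the number of chains
(rank-normalized definitions). A fit that fails the gates is returned
flagged `converged = FALSE` rather than discarded. At desk scale the GP
length-scales often fail the ESS gate long after the coefficients have
mixed well; the flag is honest about that.

### Problem sizes

Two configurations are used throughout the package:

* **desk scale** (tests, examples): 8 sites × 60 cells, 2 chains ×
  (500 warmup + 500 draws). A full simulate–fit–check cycle takes about a
  minute on one core; coefficient recovery at this size is already
  reliable (see the parameter-recovery tests).
* **survey scale** (documented long-run mode): 32 sites × 200 subsampled
  cells, 4 chains × (2000 warmup + 3000 draws), matching the published
  analysis design. `fit_model()` takes these as plain arguments.

## The synthetic-data generator

`generate_landscape()` draws the generative inverse of the model: site CWD
z-scores uniform on [−1.5, 1.5] (spanning a hot/dry-to-cool/wet gradient);
per-cell host proportion Beta(2, 2); total density negative binomial with
mean 20 trees per cell and dispersion 5; mean host height lognormal
(median 18 m, log-sd 0.3); cell basal area derived from density times the
per-tree basal area at the cell's mean height through a linear
height–DBH allometry (2 cm per m + 2 cm), times a lognormal allometric
residual (log-sd 0.4). The residual matters: height-to-DBH allometries
are inherently noisy, and without it cell basal area would be an exact
function of density and height, leaving the height/density/basal-area
block of the design matrix nearly collinear (R² ≈ 0.98) and those
coefficients jointly unidentifiable. These defaults bracket typical
field means for Sierra Nevada yellow pine/mixed-conifer stands (roughly 19
trees and 18 m mean height per 0.04-ha plot). The default coefficient
vector is the set of reported posterior medians for this system, the
default zero-inflation is 0.1, and the default GP has amplitude 0.5
(log-odds) and length-scale 40 m — half a cell diagonal to two cells, a
plausible range for beetle-driven spatial clustering of mortality. The
intercept −1 puts overall mortality near the observed 26%.

Host counts are `round(total × proportion)`; cells with no hosts are
generated but flagged ineligible, since their mean host height (a required
covariate) is undefined. The GP field is drawn exactly (dense covariance +
Cholesky, jitter escalating from 1e-8 to at most 1e-4 before failing with
the site named). All latent quantities — the GP draw, the true mortality
probability, the zero-inflation indicator — are kept next to the data.

What the generator deliberately does *not* emulate: measurement error in
tree detection and classification (downstream stages are tested against
their own fixtures instead), beetle population dynamics through time,
covariate spatial autocorrelation (only the response is spatially
structured), and non-ponderosa dead trees (the generator, like the model,
treats dead as host). Passing recovery tests on this generator therefore
demonstrates that the *model and sampler* are correct, not that the
survey pipeline is free of measurement bias.

`generate_stem_map()` (homogeneous Poisson process), `render_chm()`
(max-composed paraboloid crowns) and `render_crown_spectra()` (live
green-vegetation vs dead dry/gray reflectance templates with species
offsets and Gaussian noise) provide ground-truth fixtures for the
detection, metrics and classification stages. Dead crowns carry no species
offsets — standing dead trees are not spectrally distinct by species,
which is exactly why the classification cascade assigns all dead crowns to
the host species.

## Numerical and design choices

* **ZIB log-pmf** is computed in log space with log-sum-exp for the
  $y = 0$ mixture; it is exactly normalized (tested to 1e-12).
* **Percentiles** (height p25/p75) use linear interpolation between order
  statistics (R type 7), the common default in this ecosystem; the choice
  matters only at very small $n$.
* **Tall-tree count** uses the strict inequality height > 15 m.
* **Neighbour distances** are 2-D horizontal, within the clipped plot only,
  with no edge correction — a known upward bias shared with the field
  protocol being emulated.
* **Detector tie-breaks**: on plateaus, the first pixel in row-major order
  wins; a pixel must reach the window maximum to be a treetop.
* **5%-of-best tally**: a metric counts once if either the correlation or
  the RMSE criterion is met (default), or only if both are
  (`mode = "both"`); the correlation criterion is undefined when the best
  correlation is non-positive, and such metrics are excluded from it.
  Tally ties break by higher mean correlation, then input order.
* **Crown pixel rule**: pixel-centre-in-geometry, deterministic; indices
  are computed from crown band *means* (the ten-variable design), with a
  per-pixel-then-average mode behind a flag.
* **Height calibration** is linear OLS per live/dead status, fitted only on
  pairs with drone height > 20 m but applied to all trees, floored at 0;
  the >20 m restriction reflects that tall trees dominate the bias signal
  while the correction must cover the whole height range.
* **Gridding**: cells are half-open intervals; dead trees count as hosts in
  the trial count, the host proportion and the mean host height by default
  (live-only alternatives behind flags); cells without hosts are excluded
  from the model table, and this exclusion is the single most consequential
  filtering rule in the pipeline — it is flagged in the output rather than
  silent.
* **GLM limit**: with $\sigma_j = 0$ and $p = 0$ the model collapses to a
  binomial GLM; the package's MAP (likelihood-only) matches an independent
  IRLS fit to better than 1e-3, a strong end-to-end check of the
  likelihood implementation.

## Known limitations

* The length-scale Metropolis step mixes slowly on small sites; treat
  per-site $\ell_j$ posteriors at desk scale as exploratory.
* The reference treetop detector is a plain moving-window local-maxima
  filter intended for benchmarking infrastructure, not a competitive
  detection algorithm.
* The default classifier is ridge-penalized (multinomial) logistic
  regression; boosted logistic regression or regularized discriminant
  analysis can be plugged in through the same fit/predict contract but are
  not re-implemented here.
* No edge-corrected spatial statistics, no approximate GPs, no model
  comparison (LOO/WAIC), and no hurdle or negative-binomial variants.
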