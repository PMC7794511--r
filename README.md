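# pipomort

Bark-beetle-induced ponderosa pine mortality from individual-tree survey
data: forest-structure metrics, detector benchmarking, crown spectral
classification, calibration, gridding, and a spatial zero-inflated binomial
mortality model.

## What this package is for

During and after the 2012–2016 Californian hot drought, the western pine
beetle (*Dendroctonus brevicomis*) killed ponderosa pine (*Pinus
ponderosa*) across the Sierra Nevada at rates that coarse climate variables
alone cannot explain. The scientific question is a cross-scale one: how do
broad-scale water stress (climatic water deficit, CWD) and local forest
structure and composition — host proportion, host tree size, stand density,
basal area — jointly shape the probability that a host tree dies?

`pipomort` is for ecologists and biometricians who have (or can simulate)
individual-tree data — stem maps, canopy-height rasters, crown reflectance —
and want to run that question end to end:

1. **structure metrics** — the seven plot-level metrics used to validate
   tree detection (counts, height summaries, neighbour distances);
2. **detection benchmarking** — Pearson r / RMSE / median error of aerial
   vs ground metrics, and the 5%-of-best tally rule for choosing a
   detector, plus a reference local-maxima detector;
3. **crown spectral classification** — five vegetation indices (NDVI,
   NDRE, RGI, CI_rededge, CI_green), per-crown mean reflectance
   extraction, and a stratified k-fold cross-validation harness with a
   pluggable classifier;
4. **calibration** — drone-to-field height bias correction by live/dead
   status, species-specific height→DBH allometry, basal area, and site CWD
   z-scoring against a species-range reference;
5. **gridding** — aggregation of classified trees to 20 × 20 m cells and
   construction of the standardized model table;
6. **model** — the zero-inflated binomial regression with a per-site exact
   Gaussian process, fitted by Hamiltonian Monte Carlo;
7. **synthetic data** — a generator producing landscapes, stem maps,
   canopy rasters and crown spectra with known ground truth, so every
   stage is testable without any field download.

## The model

For cell *i* in site *j*, with *n<sub>i</sub>* host trials (live ponderosa
plus all dead trees, assumed ponderosa) and *y<sub>i,j</sub>* dead trees:

```
y_ij ~ 0                  with probability p
       Binom(n_i, pi_i)   with probability 1 - p

logit(pi_i) = b0 + b1 X_cwd + b2 X_propHost + b3 X_height
            + b4 X_density + b5 X_BA
            + b6 X_cwd X_height + b7 X_cwd X_propHost
            + b8 X_cwd X_density + b9 X_cwd X_BA
            + b10 X_propHost X_height + b11 X_propHost X_density
            + b12 X_height X_BA + b13 X_cwd X_propHost X_height
            + GP_j(x_i, y_i)
```

with covariates centred and scaled pooled across sites, a global
zero-inflation probability *p*, and one exact (dense-covariance,
exponentiated-quadratic) Gaussian process per site over raw cell-centroid
coordinates. See `vignettes/mortality-pipeline.Rmd` for priors, sampler
design and all numerical choices.

## Worked example

Simulate an 8-site landscape at the default generating conditions (the
reported posterior-median effect sizes for this system), fit the model, and
check it against the truth it was generated from:

```r
library(pipomort)

cfg  <- synthetic_config(n_sites = 8, grid_side_cells = 8,
                         cells_per_site = 60, seed = 42)
land <- generate_landscape(cfg)
land
#> <pm_landscape> 8 sites, 480 cells (477 with host trees)
#>   dead fraction over host trials: 0.335; zero cells: 0.338

dat <- zib_data(land$model_table)
fit <- fit_model(dat, chains = 2, warmup = 500, draws = 500, seed = 42)
eff <- summarize_effects(fit)
eff[eff$parameter %in% c("cwd", "prop_host", "host_height",
                         "cwd_x_host_height"), ]
#>           parameter median  l66  u66  l95  u95 sign_certain
#> 2               cwd   0.81 0.63 0.95 0.46 1.13         TRUE
#> 3         prop_host   0.81 0.75 0.86 0.68 0.93         TRUE
#> 4       host_height   0.39 0.31 0.46 0.25 0.53         TRUE
#> 7 cwd_x_host_height   0.44 0.36 0.52 0.28 0.62         TRUE

posterior_predictive_check(fit, n_rep = 50, seed = 1)
#> <zib_ppc> observed zero-cell fraction 0.338; replicated 0.294-0.409
#>   (central 90%: 0.303-0.383)
```

Reading the output: the landscape was generated with CWD effect 0.85, host
proportion 0.68, host height 0.25 and CWD × height 0.54 (log-odds per
standard deviation of the covariate). The posterior medians land near the
truth, every 95% credible interval here covers it, all four signs are
certain, and the posterior predictive replicate of the zero-cell fraction
brackets the observed one — the model reproduces the feature (excess zero
cells) it was built to capture. A positive `cwd_x_host_height` is the
cross-scale interaction of interest: larger host trees raise mortality
*more* in hotter, drier sites.

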