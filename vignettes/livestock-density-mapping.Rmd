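---
title: "Model-based mapping of livestock-to-human density: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based mapping of livestock-to-human density: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(herdmaps)
```

## The problem

Household surveys (DHS, MICS, LSMS and national panel surveys) record how
many cattle or pigs the sampled households keep, georeferenced to the
centroid of the survey cluster (enumeration area). herdmaps turns such
cluster-level counts into gridded, time-resolved surfaces of livestock
*density*, defined throughout as the ratio of livestock to humans — the
expected livestock count in a cell occupied by exactly one person. Tying
livestock to the human population rather than to land area makes the
product directly useful for zoonotic-exposure work, where what matters is
how many animals people live with.

Census extracts that are geolocated only to administrative areas (the
common situation for fragile states) cannot support the point-level model;
for those, the package provides a design-based small-area-estimation (SAE)
stage instead.

## The cluster-level model

For cluster $i$ with livestock count $Y_i$ and human count $D_i$,

$$Y_i \mid \mu_i, p \sim \mathrm{ZIP}(\mu_i, p), \qquad
\mu_i = \exp\!\big(\alpha_0 + \mathbf{x}_i'\boldsymbol\beta + S(\mathbf{s}_i)
+ \omega_{t(i)} + \epsilon_i + \gamma_{k(i)} + \eta_{t(i)}
+ u(\mathbf{s}_i, t(i)) + \log D_i\big),$$

a type-1 zero-inflated Poisson: with probability $p$ the cluster is a
structural zero (no livestock kept at all), otherwise the count is Poisson.
The terms are

* $\mathbf{x}_i$ — design covariates sampled at the cluster location:
  urban/rural status, protected area, water body (all binary), and
  elevation (z-scored internally; the reported coefficient is per SD).
* $S(\cdot)$ — a Matérn ($\nu = 1$) Gaussian field for residual spatial
  structure, approximated as a Gauss–Markov random field through the SPDE
  finite-element discretization (below).
* $\omega_t$ — a random walk (order 2 by default, order 1 in menu model 6)
  over calendar years.
* $\epsilon_i, \gamma_k, \eta_t$ — iid cluster, survey, and year effects,
  treated as measurement error and therefore excluded from prediction.
* $u(\mathbf{s}, t)$ — a separable space–time interaction: an SPDE field
  with an AR(1) structure across years (Kronecker precision).
* $\log D_i$ — offset; dropping it at prediction time yields density.

The model block writes $p_i$ per cluster, but the type-1 likelihood carries
one mixing weight; the implementation uses a single shared $p$ with a
logit-normal prior (mean $-1$, SD $1$ on the logit scale, i.e. a mildly
zero-light prior), and this choice is surfaced here deliberately.

### The SPDE discretization

The study region is triangulated with an inner mesh (maximum edge 0.3°)
over the country and a coarser outer belt (maximum edge 0.6°) extending 1°
beyond it, which pushes boundary artefacts of the SPDE away from the data.
The mesh generator lays a structured right-triangle grid satisfying the
outer limit and refines every triangle touching the country polygon by
Rivara longest-edge bisection until the inner limit holds; bisection keeps
the triangulation conforming and its angles bounded. Only the maximum edge
lengths and the extension are contractual; vertex placement is an
implementation detail.

With piecewise-linear basis functions, mass matrix $C$ (lumped to a
diagonal, the standard choice that keeps the precision sparse) and
stiffness matrix $G$, the Matérn ($\nu = 1$) weights have precision

$$Q = \tau^2\big(\kappa^4 C + 2\kappa^2 G + G C^{-1} G\big), \qquad
\kappa = \sqrt{8}/\rho_s, \quad \tau^2 = \big(4\pi\kappa^2\sigma_s^2\big)^{-1},$$

so that $\rho_s$ is the distance at which correlation falls to about
0.14 and $\sigma_s$ is the marginal standard deviation. Coordinates are
treated as planar degrees (no great-circle correction): all of the model's
length scales are specified in degrees near the equator, and the package
follows that convention. The test suite checks $Q^{-1}$ against the closed
form $\kappa d\,K_1(\kappa d)$ at random vertex pairs (error below 0.05)
and the marginal variance within 10% at mesh interiors.

### Priors

All hyperpriors are penalized-complexity (PC) priors, each an exponential
penalty on the distance from a base model, calibrated by one printed tail
statement:

| parameter | calibration | default |
|---|---|---|
| spatial range $\rho_s$ | $P(\rho_s < 0.3^\circ) = 0.05$ | joint PC Matérn, $d = 2$ |
| spatial SD $\sigma_s$ (and $\sigma_{st}$) | $P(\sigma > 1) = 0.05$ | exponential, rate $-\log(0.05)$ |
| iid SDs $\sigma_\epsilon, \sigma_\gamma, \sigma_\eta$ | $P(\sigma^2 > 0.5) = 0.01$ | converted to the $\sigma$ scale |
| AR(1) correlation $\rho_t$ | $P(\rho_t > 0.5) = 0.8$ | base model $\rho = 1$ (`cor1`) |
| RW precision | Gamma(1, 5·10⁻⁵) on the precision | software-default convention |
| fixed effects | Normal(0, 1000) | diffuse |

Two documented judgement calls. First, the AR(1) base model is not stated
in the sources; `cor1` (base at perfect correlation, shrinking the
interaction toward a purely spatial field) matches the lineage of software
defaults this model family comes from, and `cor0` remains available.
Second, the interaction field $u$ shares the spatial range $\rho_s$ with
$S$ and carries its own standard deviation; giving $u$ a free range as well
roughly doubles the spatial hyperparameter count for little identifiable
gain at survey-scale data.

A useful interpretability check on the $P(\sigma > 1) = 0.05$ prior: with
$\theta \mid \sigma \sim N(0, \sigma^2)$, the induced 95% interval of the
residual rate ratio $e^\theta$ is $(0.37, 2.72)$ — a cluster may plausibly
hold about a third to nearly three times the livestock its covariates and
neighbours suggest. The package computes this by quadrature and by Monte
Carlo (`implied_rate_ratio_interval()`); both routes agree to 0.01. Under
the SAE calibration $P(\sigma > 1) = 0.01$ the same construction gives
about $(0.52, 1.92)$, not the $(0.36, 2.71) \approx e^{\pm 1}$ sometimes
quoted for it; the package reports the principled quantity and flags the
discrepancy rather than reproducing it.

### Inference: Laplace-within-Metropolis

Conditional on the hyperparameters
$\theta = (\rho_s, \sigma_s, \sigma_\tau, \sigma_\epsilon, \sigma_\gamma,
\sigma_\eta, \sigma_{st}, \rho_t, p)$, the latent field
$x = (\alpha_0, \boldsymbol\beta, S, \omega, \epsilon, \gamma, \eta, u)$
has a log-concave-enough conditional posterior that a sparse Newton ascent
(with step halving and a curvature clip at $10^{-8}$ where the
zero-inflated likelihood is locally convex) finds its mode in a handful of
iterations; the Gaussian (Laplace) approximation at that mode gives both a
sampler for $x$ and an approximation of the marginal likelihood
$\pi(y \mid \theta)$. The hyperparameter posterior
$\pi(\theta \mid y) \propto \pi(y \mid \theta)\,\pi(\theta)$ — at most nine
dimensions — is then explored by random-walk Metropolis
started at its mode: a Nelder–Mead search locates the mode, a
central-difference Hessian there calibrates the proposal covariance
(scaled by the usual $2.38^2/d$), and a short warmup only rescales the
global step toward 30% acceptance. Mode-matched proposals give an order
of magnitude more effective samples per evaluation than cold-start
adaptation on this target. A `method = "map"` fast path stops at the mode
with the Gaussian approximation and is used inside cross-validation loops.

Numerical choices worth recording: sum-to-zero constraints on the
rank-deficient temporal structures (both the constant and the linear
contrast for RW2, the constant for RW1, ICAR and the iid year effect) are
imposed softly, by adding precision $10^6$ on projections onto the exact
null-space basis; because the basis spans the null space exactly, the
$\sigma$-dependence of the generalized log-determinant stays exact. The
linear predictor is capped at 30 before exponentiation. Degenerate
zero-area triangles, islands in the county adjacency, single-class
training data and years outside the fitted span are all hard errors, not
silent fixes.

The engine's contract is accuracy against independent oracles, which the
test suite enforces: on a 30-cluster intercept-only Poisson model the
posterior mean of $\alpha_0$ matches one-dimensional dense quadrature
within 0.05, and simulation-based calibration on an intercept-plus-nugget
model (200 replicates, 19-level ranks, $\chi^2$ at $\alpha = 0.01$) checks
that the approximate posterior is neither over- nor under-dispersed.

### Prediction

`predict_density()` evaluates, per posterior draw and per 0.017° grid cell,
$\exp(\alpha_0 + \mathbf{x}'\boldsymbol\beta + S + \omega_t + u_t)$ — no
iid effects, no offset — and summarizes each cell by the posterior median
and the width of the central 95% interval. No cells are masked as
unsuitable; water, urban and protected cells are flagged instead so users
can make their own exclusions. Rasters are written as plain-text ESRI
ASCII grids (one file per species–year–band), a format every GIS stack
reads; county-level SAE output is written as CSV plus GeoJSON.

### Model menu and cross-validation

Six candidate models vary the fixed effects (intercept only, then adding
urban/rural, protected areas, water bodies, elevation) with model 6
swapping the RW2 year effect for RW1. A restricted variant for sparse
countries drops the space–time interaction and the iid survey and year
effects. Cross-validation holds out a random 25% of each survey's
clusters, allocated evenly across district-by-urbanicity strata (fold
sizes within a stratum differ by at most one); the held-out clusters'
densities are predicted without iid effects and scored by
$\mathrm{MSE} = \tfrac1N \sum_i (y_{\mathrm{obs},i} - y_{\mathrm{pred},i})^2$
on the density scale. The scheme is reported per survey — the left-out
unit of interpretation — while refitting per fold across surveys
(`mode = "global"`); a literal leave-out-per-survey mode is also
implemented. Selection takes the cluster-weighted minimum, breaking exact
ties toward fewer fixed effects and then the smaller model id.

## The SAE stage

Where data are county-level census extracts, each county's density is
estimated by the Horvitz–Thompson ratio
$\hat\mu_c = \sum w_i Y_i / \sum w_i D_i$ with inverse-probability
weights, its design variance by household-level with-replacement Taylor
linearization (the extract's true design is not published; a delete-one
jackknife cross-check within 10% is part of the tests), and the log
estimate $\hat\theta_c = \log\hat\mu_c$ carries delta-method variance
$\widehat{\mathrm{var}}(\hat\mu_c)/\hat\mu_c^2$. Smoothing treats
$\hat\theta_c$ as Gaussian with known variance and fits
$\hat\theta_c = \beta_0 + \epsilon_c + S_c$ with iid and ICAR county
effects under $P(\sigma > 1) = 0.01$ PC priors; because the likelihood is
Gaussian, the marginal likelihood of the two hyperparameters is exact, and
the same Metropolis machinery applies. Counties with no data (the
missing-county case) or a zero ratio (no finite log) are excluded from the
likelihood and predicted from $\beta_0 + S_c$. Reported summaries are the
posterior median and SD of $e^{\theta_c}$.

## The synthetic-data generator

Because the real microdata are access-restricted, every stage is exercised
against `synthetic_config()` worlds drawn **from the model itself**:

* covariate rasters with "cities" driving correlated population-density
  and nighttime-lights surfaces (so the urbanicity logistic classifier is
  learnable), plus binary protected/water layers thresholded at requested
  fractions and a smooth elevation surface;
* cluster surveys with uniform locations, grid-partition districts,
  human counts $D_i \sim \max(1, \mathrm{Poisson}(\text{households} \times
  \text{mean household size}))$, latent fields drawn through the same
  sparse SPDE precision the fit uses, and ZIP counts from the full linear
  predictor — with every latent draw recorded for recovery tests;
* weighted household censuses over grid counties with an ICAR-structured
  truth, sampled by Poisson sampling either uniformly or with inclusion
  probabilities increasing in livestock holdings (informative), so the
  weighted ratio is design-unbiased while the unweighted one is visibly
  biased.

Generator defaults are the package's stated study conditions: five annual
surveys of 160 clusters (800 cluster-years), $\alpha_0 = -2$,
$\sigma_s = 0.5$, $\rho_s = 0.5^\circ$, $\sigma_\tau = 0.2$,
$\sigma_\epsilon = 0.3$, $\sigma_\gamma = 0.2$, $\sigma_\eta = 0.1$,
$\sigma_{st} = 0.2$, $\rho_t = 0.7$, $p = 0.1$, 25 households per cluster
with mean household size 4.5. The within-cluster household-count
distribution is not pinned down by the survey documentation, so it is a
parameter, not a constant. Missingness is completely at random at a
configurable rate — the sources state only how missing counts are
excluded, not how they arise.

What the generator does *not* emulate: settlement patterns (locations are
uniform), DHS jitter displacement (off by default and out of scope), or
spatially-structured missingness. Passing recovery tests therefore shows
the estimator chain is self-consistent at realistic sizes and noise
levels; it does not certify behaviour under location error or informative
missingness in real surveys.

## Verification experiments and problem sizes

The acceptance suite runs four simulation experiments, sized to finish on
one CPU in well under half an hour total:

* **Parameter recovery** — 20 replicate worlds at the default 800 clusters
  and 5 years on a 3° country (six range-lengths across, so the range is
  identifiable; on a domain only four ranges wide the Matérn
  $\sigma$–$\rho$ likelihood ridge plus the range prior bias both upward),
  fitting the same model that generated the data; 80% posterior intervals
  must cover the true $\alpha_0$, $\sigma_s$ and $\rho_s$ in at least 60%
  of replicates each.
* **Model selection** — 10 replicate worlds generated from menu model 6
  (RW1, all four covariates) on a 1.2° country with six annual surveys of
  60 clusters; binary covariates are given prevalences 0.30/0.25/0.15 and
  sub-mesh spatial scales so the Matérn field cannot absorb them (with a
  smooth covariate the field and the coefficient are confounded — a real
  feature of these models, not an artefact), the year path is rough
  ($\sigma_\tau = 0.8$; rougher paths push the raw-density MSE into a
  heavy-tailed regime where a few extreme clusters dominate the score),
  and the true model must attain the lowest
  cluster-weighted MSE in at least 7 of 10 replicates.
* **SAE smoothing** — 25 replicate censuses over 40 counties with about 8
  sampled households per county (the unstable-direct-estimate regime SAE
  exists for); the smoothed posterior medians must beat the direct
  estimates in squared error against the known truth in at least 80% of
  replicates.
* **Surface recovery** — the predicted median surface must correlate above
  0.7 with the true simulated density surface.

The worked prior quantities (the $(0.37, 2.72)$ interval and the three
calibration probabilities) are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

* The latent-field posterior is a Gaussian approximation at the
  conditional mode; extreme zero-inflation with tiny counts can make the
  ZIP conditional multimodal, which Metropolis over $\theta$ does not
  repair. The SBC test bounds this risk at the sizes used, not universally.
* Cluster coordinates are taken at face value (enumeration-area
  centroids); jitter correction is explicitly out of scope.
* The range/SD pair of the interaction field is tied to the main field's
  range (see Priors) — countries where the interaction operates at a
  different scale would need that assumption revisited.
* Planar-degree geometry is adequate near the equator but degrades with
  latitude; no great-circle correction is applied.
* Menu models differing only in smooth covariates or temporal order are
  genuinely hard to separate by cluster-level CV (spatial confounding);
  the selection experiment documents the regime where separation is
  achievable, and ties are broken toward parsimony.

## A small worked pipeline

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(seed = 7, true_params = list(sigma_survey = 0,
                                                     sigma_year = 0,
                                                     sigma_st = 0))
covs <- simulate_covariates(cfg)
mesh <- build_mesh(cfg$boundary, inner_max_edge = 0.25)
clusters <- simulate_survey(cfg, covs, mesh)

fit <- fit_zip_model(clusters, mesh, model_spec(2, restricted = TRUE),
                     control = fit_control(iter = 380, warmup = 150, seed = 42))
tidy(fit)

draws <- posterior_sample(fit, n = 500)
grid <- make_grid(cfg$boundary, resolution = 0.05, covariates = covs)
surface <- predict_density(draws, grid, year = 2008)
autoplot(surface)
```
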