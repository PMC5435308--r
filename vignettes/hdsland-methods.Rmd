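---
title: "Hierarchical distance sampling for landscape-scale prey density: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical distance sampling for landscape-scale prey density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hdsland` estimates the above-ground density of small mammals (sciurids and
leporids) from point- and line-transect distance-sampling surveys, relates
that density to environmental covariates measured at two focal scales, and
projects the fitted model onto covariate rasters as a density surface. This
vignette is the package's own account of the statistical machinery: the
model, the selection procedure, the bootstrap diagnostics, the synthetic
data generator that the test suite runs against, and the numerical choices
underneath.

## The hierarchical model

Surveys yield, for each transect $i$ on each sampling occasion, the
distances to detected individuals. After truncation the distances are
grouped into $J$ bins with cutpoints $0 = c_0 < c_1 < \dots < c_J = w$.
The model has two coupled components:

* **Abundance.** The latent number of individuals in the covered area of
  transect-occasion $i$ is $N_i \sim \text{Poisson}(\lambda_i)$ with
  $\log \lambda_i = x_i^\top \beta + \log(\text{effort}_i)$. The effort
  offset makes $\beta$ per-station (point transects) or per-metre (line
  transects) so that transects of different length are comparable. Every
  abundance model carries the sampling-occasion factor (first occasion as
  reference): the populations are not assumed closed across occasions, so
  each occasion is treated as an independent event.
* **Detection.** An individual at distance $x$ is detected with
  probability $g(x)$, either half-normal
  $g(x) = \exp(-x^2 / 2\sigma^2)$ or hazard-rate
  $g(x) = 1 - \exp(-(x/\sigma)^{-b})$, with
  $\log \sigma_i = v_i^\top \alpha$. The hazard-rate shape $b$ is shared
  across rows and fitted on the log scale; covariates act on $\sigma$
  only.

Individuals are uniform in area around a point (density $2x/w^2$) and
uniform in perpendicular distance from a line (density $1/w$), so the
probability that an individual in the covered area falls in bin $j$ *and*
is detected is

$$\pi_{ij} = \int_{c_{j-1}}^{c_j} \frac{2x\,g(x;\sigma_i)}{w^2}\,dx
\quad\text{(point)},\qquad
\pi_{ij} = \int_{c_{j-1}}^{c_j} \frac{g(x;\sigma_i)}{w}\,dx
\quad\text{(line)}.$$

Because a Poisson total thinned independently into bins gives independent
Poisson bin counts, the marginal likelihood factorizes:
$y_{ij} \sim \text{Poisson}(\lambda_i \pi_{ij})$, independently over bins.
This multinomial–Poisson marginalization is what the package maximizes;
the test suite verifies it against brute-force summation over the latent
$N$ on every random small instance it generates.

Density in individuals/km² is $\hat\lambda_i$ divided by the covered area:
$\pi w^2$ per point station and $2 L w$ per line of length $L$ (both
sides). Standard errors for occasion and overall mean densities come from
the delta method on $\beta$.

## Data preparation

* **Truncation.** The farthest 10% of point-transect and 5% of
  line-transect observations are dropped (`ceiling(fraction * n)`
  observations), $w$ is the maximum retained distance, and observations
  tied with the cut distance are retained — a deterministic, conservative
  convention.
* **Groups.** Observers record the distance to the centre of a group and
  its size; groups are expanded to individuals at the shared distance
  before fitting. Cluster-size covariance is deliberately not modelled: a
  documented limitation, and in practice clustered detections surface as
  over-dispersion that the GOF machinery (below) is designed to catch.
* **Binning.** Ten equal-width bins to $w$ by default (`n_bins` is a
  config knob). Coarsening bins can only increase the maximized
  log-likelihood (the coarse data are a function of the fine data, and
  the product-Poisson likelihood drops the conditional factor), so
  criteria are only compared between models fitted to the same binning.

## Two-step covariate selection

Covariates live in a catalog with a category (vegetation, climate,
topographic, anthropogenic) and are offered at two focal scales — the mean
within 250 m and 1000 m circular windows, computed by `focal_mean()` from
30 m rasters and standardized to the raster's own mean and SD.

1. **Univariate screening.** Each covariate, at each scale, is fitted as
   the sole predictor of abundance (detection held intercept-only,
   abundance base `~ occasion`) and of detection (abundance held at
   `~ occasion`). For abundance, covariates whose best-scale AICc is at or
   below the null model's are retained (ties at the scale contest go to
   the 1000 m scale); for detection only the single best covariate is
   carried forward.
2. **Collinearity.** Pairs with Pearson $|r| > 0.7$ are resolved by
   keeping the lower-AICc member, applied greedily in ascending AICc
   order so the best-supported covariate always survives; then variance
   inflation factors ($\text{VIF}_k = 1/(1-R^2_k)$) are computed on the
   surviving set and the largest-VIF covariate is dropped until all are
   $\le 4$.
3. **Candidate set.** A fixed grammar, not an all-subsets search: a
   global model, one model per covariate category, a "top mix" with the
   best covariate of each category, and the occasion-only null — occasion
   in every abundance candidate. Detection candidates: the top covariate
   continuous, as a 3-level equal-width categorical (cut on the sampled
   minimum and maximum, a self-contained choice since the sampled frame
   is what the model sees), occasion-only, and occasion plus the
   categorical. Empty categories collapse to occasion-only and are
   flagged; structurally identical candidates are de-duplicated.
4. **Three-phase contest.** Detection candidates are ranked under
   occasion-only abundance; abundance candidates are ranked under the
   winning detection structure; the winning abundance structure is then
   re-run against every detection candidate to confirm or revise the
   detection choice. Ranking uses
   $\text{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)$ with $n$ the number of
   transect-occasion rows (an explicit convention — the effective sample
   size of a hierarchical model is not well defined), or QAICc when
   over-dispersion has been estimated, with $K' = K + 1$ counting
   $\hat{c}$.

The detection *family* is chosen before all of this by fitting both
families to each occasion separately and keeping the family that wins the
per-occasion AICc contest most often; ties break to the half-normal, the
more parsimonious family.

## Goodness of fit and over-dispersion

The fit statistic is the Freeman–Tukey sum of squares
$\text{SSE} = \sum_{ij} (\sqrt{y_{ij}} - \sqrt{\hat\mu_{ij}})^2$. The
parametric bootstrap simulates $B$ datasets from the fitted cell means
(default $B = 1000$), refits each one (warm-started at the original
optimum), and reports
$p = (1 + \#\{\text{SSE}^*_b \ge \text{SSE}_\text{obs}\})/(B+1)$ — never
exactly zero — and $\hat{c} = \text{SSE}_\text{obs}/\overline{\text{SSE}^*}$.
When $\hat{c} > 1$, coefficient covariance is multiplied by $\hat{c}$ (so
standard errors inflate by $\sqrt{\hat{c}}$, the Burnham–Anderson
convention for "inflating standard errors by $\hat{c}$", whose wording is
loose), selection is re-run under QAICc, and occasion densities are
re-estimated by a nonparametric bootstrap that resamples *sites* with
replacement — the site is the resampling unit so within-site dependence
is preserved.

Two statistical properties of this machinery are worth knowing, both
established while building the calibration tests:

* **Sparse cells make the p-value conservative.** When per-cell
  expectations are far below 1, the Freeman–Tukey statistic is nearly a
  deterministic function of the fitted parameters, so the observed SSE
  sits in the middle of its own bootstrap distribution almost regardless
  of the data. The p-value is approximately uniform only in the
  large-count regime — which is where the motivating surveys operate
  (thousands of detections per species). The calibration tests therefore
  run at per-cell expectations of roughly 1–5.
* **Detection thinning dilutes latent over-dispersion.** If latent
  abundance is over-dispersed with variance $\phi\lambda$, a bin keeping
  a fraction $\pi_j$ of individuals has count dispersion
  $1 + (\phi - 1)\pi_j$: with fine bins and modest detection, $\hat{c}$
  cannot see even substantial latent over-dispersion. The
  misspecification test accordingly surveys with high detection and
  coarse bins. Conversely, a $\hat{c}$ near 1 on real fine-binned data
  is weak evidence of latent Poisson behaviour.

## Spatial prediction

`predict_surface()` applies $\hat\beta$ cell-wise to co-registered
covariate rasters: $\hat{D}(s) = \exp(x_s^\top \hat\beta)$ divided by the
per-unit-effort covered area, in individuals/km². The occasion factor is
fixed at a configurable reference occasion (default: the first), since a
map depicts one occasion's conditions. Standardization statistics are the
ones recorded at fitting time, and rasters should first be clamped with
`constrain_range()` to the sampled covariate range so the log-linear
model never extrapolates; the SE surface is the delta-method
$\hat{D}(s)\sqrt{x_s^\top \hat\Sigma x_s}$ with the $\hat{c}$-inflated
covariance when one was estimated.

## The synthetic-data generator

There is no public dataset behind the motivating study, so the package
carries a first-class simulator whose defaults emulate the study design:

* **Landscapes**: Gaussian random fields (white noise convolved with a
  Gaussian kernel on a torus, standardized), at 30 m resolution, averaged
  into 250 m and 1000 m focal scales — the two extents offered to
  screening.
* **Design**: sites carrying six line transects, each with four point
  stations spaced 333 m apart; five sampling occasions labelled as a
  fixed factor with the first occasion as reference.
* **Observations**: Poisson latent abundance with log-linear covariate
  effects, individuals placed uniformly in the sampled geometry, grouped
  into clusters of size $1 + \text{Poisson}(\bar{s} - 1)$ sharing one
  distance (the last cluster truncated so the latent total is honoured),
  each cluster detected as a unit by the half-normal or hazard-rate
  function. Truth (per-row $\lambda$ and $N$, generating coefficients) is
  returned alongside and never read by estimation code.

What it does **not** emulate, and what passing tests therefore cannot
certify about field data: animal movement and double counting, temporary
emigration (availability $< 1$ — estimates are above-ground density, not
total density), off-transect opportunistic observations, observer
heterogeneity, species misidentification, and any real geodesy (the grid
is planar, no CRS). Every simulation function takes an explicit seed and
restores the caller's RNG state; there is no hidden global randomness.

```{r}
library(hdsland)
veg <- generate_landscape(110, 110, 30, 300, seed = 1)
veg_1000 <- standardize_raster(focal_mean(veg, 1000))
design <- make_survey_design(8, extent = c(0, 3300, 0, 3300), seed = 2)
covs <- sample_site_covariates(list(veg_1000 = veg_1000), design)
sim <- simulate_survey(design, covs, abundance = ~ veg_1000 + occasion,
                       beta = c(1.5, -0.5, rep(0.1, 4)), detection = ~1,
                       alpha = log(45), family = "halfnorm", w = 140,
                       n_occasions = 5, mean_group_size = 2, seed = 3)
```

## Numerical choices

* **Quadrature.** The exported `cell_probabilities()` integrates each bin
  with the adaptive Gauss–Kronrod integrator (`stats::integrate`,
  relative tolerance $10^{-8}$), splitting the first bin at $\sigma/10$
  for the hazard family's integrable shoulder. Inside the likelihood a
  vectorized fixed Gauss–Legendre rule (25 nodes per panel; hazard bins
  split into geometric sub-panels toward zero) evaluates all rows at
  once on shared nodes; the suite ties the two paths together at
  $10^{-8}$ and both to closed forms where they exist.
* **Optimization.** BFGS with analytic gradients for $\beta$, $\alpha$
  and $\log b$ (differentiation under the integral on the same nodes),
  objective relative tolerance $10^{-12}$, up to three deterministic
  jittered restarts before declaring failure. Starting values: abundance
  intercept at the log mean count per unit effort, $\log\sigma$ at the
  log mean observed distance, $\log b = \log 2$, everything else 0.
* **Covariance.** Central differences of the analytic gradient give the
  observed information; its inverse is the coefficient covariance.
* **Degenerate inputs.** All-equal distances truncate to "keep
  everything"; a dataset with zero detections cannot infer $w$ and says
  so; a detection-covariate tercile with no observations drops the
  categorical candidates rather than fitting a rank-deficient design;
  all-zero counts drive the density to zero with an undefined SE rather
  than an error.
* **Determinism.** Identical configs (seeds included) produce
  byte-identical numeric outputs; survey CSVs print doubles with 17
  significant digits so a write/read cycle is exact.

## Problem sizes in the test suite

The suite exercises the full method at desk scale, chosen to be the
smallest sizes at which each property is expected to hold: likelihood
oracle equivalence on 100 random instances with total counts $\le 60$;
parameter recovery over 100 replicate studies of 200 point transects
$\times$ 5 occasions (nominal 95% CI coverage within binomial tolerance);
GOF calibration over 200 replicates at $B = 100$ in the large-count
regime, and 1.5$\times$ over-dispersion detection over 60 replicates at
high detection with coarse bins; selection sanity over 50 replicates of a
vegetation-driven truth; and a bundled 144-station, two-occasion fixture
for the end-to-end pipeline, which its grouped detections push through
the over-dispersion branch (QAICc re-selection, SE inflation, site
bootstrap).

## Known limitations

Cluster size is not a covariate of detection; density is above-ground
density (no availability correction); the abundance distribution is
Poisson only (over-dispersion is corrected post hoc via $\hat{c}$, not
modelled as negative-binomial); no temporary emigration or movement; no
model averaging (the candidate grammar is fixed); prediction does not
mask by species range; rasters are planar grids without projection
support.
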