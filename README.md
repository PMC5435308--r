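# hdsland

Hierarchical distance sampling for landscape-scale small-mammal density.

Grassland and shrub-steppe raptors depend on sciurid and leporid prey
(prairie dogs, ground squirrels, chipmunks, rabbits and hares), yet density
estimates for these species at management-relevant scales are rare: counts
come from point- and line-transect surveys where detectability decays with
distance, and the habitat drivers of density act at neighbourhood scales a
plot survey cannot see. `hdsland` implements the full workflow for this
problem — for quantitative ecologists who need covariate-driven density
estimates and maps from distance-sampling data, and who want every step
testable against simulated truth.

## The model

Binned distance counts are fitted with the multinomial–Poisson mixture
likelihood of hierarchical distance sampling. For transect-occasion *i* and
distance bin *j*,

```
N_i  ~ Poisson(lambda_i),      log lambda_i = x_i' beta + log(effort_i)
y_ij ~ Poisson(lambda_i pi_ij(sigma_i)),   log sigma_i = v_i' alpha
```

where `pi_ij` integrates a half-normal `exp(-x^2/2sigma^2)` or hazard-rate
`1 - exp(-(x/sigma)^-b)` detection function over bin *j* under the survey
geometry (uniform in area around points, uniform in perpendicular distance
along lines). Around the likelihood sit the field's standard procedures:

* 10% (point) / 5% (line) quantile truncation of distances; groups
  expanded to individuals;
* covariates at 250 m and 1000 m focal scales, screened univariately
  against the null, pruned at Pearson |r| > 0.7 and VIF > 4;
* a fixed candidate grammar (global / per-category / top-mix / null for
  abundance; continuous / categorical / occasion structures for
  detection) ranked by AICc in a three-phase contest;
* Freeman–Tukey parametric-bootstrap goodness of fit with over-dispersion
  factor c-hat, sqrt(c-hat) standard-error inflation, QAICc re-selection
  and a site-level bootstrap of occasion densities when c-hat > 1;
* density conversion to individuals/km² (`pi w^2` per station, `2Lw` per
  line) and raster prediction with delta-method SE surfaces.

A first-class synthetic-data module simulates autocorrelated covariate
landscapes, the nested survey design (six lines of four stations spaced
333 m per site, five occasions), and observations with known truth, so
parameter recovery is a testable property. See the methods vignette
(`vignettes/hdsland-methods.Rmd`) for the statistics and the numerical
choices.

## Worked example

Simulate a six-site survey over a vegetation landscape (negative effect on
abundance, truth `beta = (1.5, -0.5, 0.2)`, half-normal `sigma = 45`), fit,
and estimate density:

```r
library(hdsland)
veg <- generate_landscape(110, 110, 30, 300, seed = 1)
veg_1000 <- standardize_raster(focal_mean(veg, 1000))
design <- make_survey_design(6, extent = c(0, 3300, 0, 3300), seed = 2)
covs <- sample_site_covariates(list(veg_1000 = veg_1000), design)
sim <- simulate_survey(design, covs, abundance = ~ veg_1000 + occasion,
                       beta = c(1.5, -0.5, 0.2), detection = ~1,
                       alpha = log(45), family = "halfnorm", w = 140,
                       n_occasions = 2, seed = 3)
d <- make_hds_data(sim$observations, sim$transects, sim$covariates,
                   geometry = "point", occasions = c("occ1", "occ2"))
fit <- fit_hds(d, ~ veg_1000 + occasion, ~1, "halfnorm")
fit
#> <hds_fit> halfnorm detection, logLik = -1075.537, K = 4, AICc = 2159.215
#> abundance (log lambda):
#>  (Intercept)     veg_1000 occasionocc2
#>       0.7494      -0.5851       0.2231
#> detection (log sigma):
#> (Intercept)
#>       3.707
estimate_density(fit)$by_occasion
#>   occasion density    se  lower  upper
#> 1     occ1  114.19 11.67  91.32 137.05
#> 2     occ2  142.73 13.68 115.92 169.55
parametric_bootstrap_gof(fit, B = 100, seed = 4)
#> <gof_result> Freeman-Tukey SSE = 456.709, bootstrap B = 100
#>   p = 0.4455, c-hat = 1.005
```

The vegetation effect (-0.585, truth -0.5) and occasion contrast (0.223,
truth 0.2) are recovered; the occasion-1 density estimate of 114.2
individuals/km² sits next to the simulation's true 115.5. The fitted
abundance intercept is smaller than the generating 1.5 because truncation
shrank the covered radius from the recorded 140 m to w = 94.8 m — the
density conversion accounts for exactly this. The estimated `sigma` of
`exp(3.707) = 40.7` m implies an average detection probability of 0.345
over the covered circle, and the bootstrap shows no over-dispersion for
these solitary simulated animals (`c-hat = 1.005`). Density maps follow
with `predict_surface(fit, list(veg_1000 = constrain_range(veg_1000,
min(covs$veg_1000), max(covs$veg_1000))))`.

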