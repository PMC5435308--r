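# Regenerates the bundled synthetic survey fixture in inst/extdata/.
# Run from the package root: Rscript tools/make-fixture.R
# The fixture is a small point-transect study (6 sites of the nested
# 6-lines-x-4-stations design, 2 occasions) simulated from a known
# half-normal model with grouped detections, so the full pipeline --
# including the over-dispersion branch -- can run on it in seconds.

for (f in list.files("R", full.names = TRUE)) source(f)

res <- 30
r_shrub <- generate_landscape(120, 120, res, 300, seed = 101)
r_tpi   <- generate_landscape(120, 120, res, 400, seed = 102)
r_well  <- generate_landscape(120, 120, res, 600, seed = 103)
layers <- list(
  shrub_250  = standardize_raster(focal_mean(r_shrub, 250)),
  shrub_1000 = standardize_raster(focal_mean(r_shrub, 1000)),
  tpi_250    = standardize_raster(focal_mean(r_tpi, 250)),
  tpi_1000   = standardize_raster(focal_mean(r_tpi, 1000)),
  well_250   = standardize_raster(focal_mean(r_well, 250)),
  well_1000  = standardize_raster(focal_mean(r_well, 1000)))

design <- make_survey_design(6, extent = c(0, 120 * res, 0, 120 * res),
                             seed = 104)
covs <- sample_site_covariates(layers, design)
stopifnot(!anyNA(covs))
# re-standardize the sampled columns so fitting sees mean-0/SD-1 covariates
covs[] <- lapply(covs, function(x) (x - mean(x)) / sd(x))

sim <- simulate_survey(
  design, covs,
  abundance = ~ shrub_1000 + tpi_250 + occasion,
  beta = c(1.4, -0.5, 0.25, 0.2),
  detection = ~1, alpha = log(45),
  family = "halfnorm", w = 140, n_occasions = 2,
  mean_group_size = 2, seed = 105, geometry = "point")

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
sim$covariates <- round(covs[design$type == "point", , drop = FALSE], 6)
sim$observations$distance_m <- round(sim$observations$distance_m, 3)
sim$transects$x <- round(sim$transects$x, 2)
sim$transects$y <- round(sim$transects$y, 2)
write_survey(sim, "inst/extdata")

writeLines(yaml::as.yaml(list(
  species = "synthetic sciurid",
  survey_dir = ".",
  geometry = "point",
  family = "auto",
  n_bins = 10L,
  covariates = list(
    list(name = "shrub", category = "vegetation"),
    list(name = "tpi", category = "topographic"),
    list(name = "well", category = "anthropogenic")),
  truncation = list(point = 0.10, line = 0.05),
  thresholds = list(r = 0.7, vif = 4),
  B = 30L, R = 20L, seed = 7L,
  occasions = c("occ1", "occ2"),
  out_dir = "fixture_out")), "inst/extdata/config.yaml")

cat("fixture:", nrow(sim$transects), "point transects,",
    nrow(sim$observations), "observed groups,",
    sum(sim$observations$group_size), "individuals\n")
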