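test_that("quantile truncation drops the stated tail and keeps ties", {
  t1 <- truncate_distances(1:100, "point")
  expect_identical(sum(t1$keep), 90L)
  expect_identical(t1$w, 90L)
  expect_true(all((1:100)[t1$keep] <= 90))
  t2 <- truncate_distances(1:20, "line")
  expect_identical(sum(t2$keep), 19L)
  expect_identical(t2$w, 19L)
  # all distances equal: nothing is strictly farther; retain everything
  t3 <- truncate_distances(rep(42, 8), "point")
  expect_true(all(t3$keep))
  expect_identical(t3$w, 42)
  # ties at the cut distance are retained
  t4 <- truncate_distances(c(1:8, 9, 9, 9), "point")  # n = 11, drop 2
  expect_identical(sum(t4$keep), 11L)   # the two "dropped" are ties at 9
  expect_identical(t4$w, 9)
  expect_error(truncate_distances(numeric(0), "point"), "no observations")
  expect_error(truncate_distances(1:10, "point", fraction = 0.6), "fraction")
})

test_that("group expansion conserves individuals", {
  obs <- data.frame(transect_id = "T1", occasion = "occ1",
                    distance_m = c(40, 10), group_size = c(5L, 1L))
  ex <- expand_groups(obs)
  expect_identical(nrow(ex), 6L)
  expect_identical(sum(ex$distance_m == 40), 5L)
  expect_true(all(ex$group_size == 1L))
  # all-singleton input is the identity apart from the group_size type
  solo <- data.frame(distance_m = c(1, 2, 3), group_size = c(1L, 1L, 1L))
  expect_equal(expand_groups(solo)$distance_m, solo$distance_m)
  expect_error(expand_groups(data.frame(distance_m = 1, group_size = 0L)),
               "group sizes")
})

test_that("the marginal Poisson likelihood matches hand-computed pmfs", {
  d0 <- manual_data(matrix(0L, 1, 1), c(0, 100))
  expect_equal(hds_nll(c(log(2), log(1e8)), d0), 2, tolerance = 1e-8)
  d3 <- manual_data(matrix(3L, 1, 1), c(0, 100))
  expect_equal(hds_nll(c(log(3), log(1e8)), d3),
               -log(3^3 * exp(-3) / factorial(3)), tolerance = 1e-8)
  expect_error(hds_nll(c(50, log(40)), d3), "overflow")
  expect_error(hds_nll(c(NA, log(40)), d3), "finite")
})

test_that("product-Poisson marginal equals brute-force summation over latent N", {
  set.seed(31)
  for (rep in 1:12) {
    J <- sample(3:6, 1)
    w <- runif(1, 60, 150)
    bins <- seq(0, w, length.out = J + 1)
    sigma <- runif(1, 20, 80)
    lambda <- runif(1, 0.5, 8)
    geom <- sample(c("point", "line"), 1)
    pi_j <- cell_probabilities(detection_spec("halfnorm", sigma),
                               distance_bins(bins), geom)
    n <- sample(2:4, 1)
    y <- matrix(rpois(n * J, lambda * rep(pi_j, each = n)), n, J)
    if (sum(y) > 60) next
    d <- manual_data(y, bins, geometry = geom)
    nll <- hds_nll(c(log(lambda), log(sigma)), d)
    oracle <- -sum(vapply(seq_len(n), function(i)
      row_loglik_enumerate(y[i, ], lambda, pi_j), numeric(1)))
    expect_equal(nll, oracle, tolerance = 1e-10)
  }
})

test_that("with detection forced on, the fit reduces to the Poisson MLE", {
  sim <- simulate_survey(flat_design(40), NULL, ~1, beta = log(6),
                         detection = ~1, alpha = log(1e6), w = 100,
                         n_occasions = 1, seed = 5)
  d <- make_hds_data(sim$observations, sim$transects, NULL, "point",
                     n_bins = 1, w = 100, occasions = "occ1")
  f <- fit_hds(d, ~1, ~1, "halfnorm", start = c(0, log(1e5)))
  expect_equal(unname(f$beta[1]), log(mean(rowSums(d$y))), tolerance = 1e-6)
})

test_that("the optimum is stationary and invariant to row order", {
  td <- tiny_dataset(n_transects = 40, n_occasions = 2, beta_cov = 0.5,
                     seed = 21)
  f <- fit_hds(td$data, ~ x1 + occasion, ~1, "halfnorm")
  refit <- fit_hds(td$data, ~ x1 + occasion, ~1, "halfnorm",
                   start = unname(c(f$beta, f$alpha)))
  expect_lt(abs(refit$logLik - f$logLik), 1e-8)
  # permute the rows: identical likelihood and coefficients
  set.seed(8); idx <- sample(nrow(td$data$y))
  dp <- td$data
  dp$y <- dp$y[idx, , drop = FALSE]
  dp$effort <- dp$effort[idx]
  dp$frame <- dp$frame[idx, , drop = FALSE]
  fp <- fit_hds(dp, ~ x1 + occasion, ~1, "halfnorm")
  expect_equal(fp$logLik, f$logLik, tolerance = 1e-6)
  expect_equal(fp$beta, f$beta, tolerance = 1e-4)
  # covariance is symmetric positive semi-definite
  expect_equal(f$vcov, t(f$vcov), tolerance = 1e-8)
  expect_true(all(eigen(f$vcov, symmetric = TRUE)$values > -1e-8))
  expect_error(fit_hds(td$data, ~ x1 + I(2 * x1), ~1), "rank-deficient")
})

test_that("small-sample information criteria follow their definitions", {
  expect_equal(aic_c(-1448.13, 6, 10000), 2908.268, tolerance = 1e-3)
  # large-n limit is plain AIC
  expect_equal(aic_c(-100, 4, 1e9), -2 * -100 + 8, tolerance = 1e-6)
  # c-hat = 1 reduces QAICc to AICc computed at K + 1
  expect_equal(qaic_c(-100, 4, 50, 1), aic_c(-100, 5, 50))
  expect_error(aic_c(-10, 6, 7), "AICc")
  # ordering is invariant to adding a constant to every logLik
  ll <- c(-120, -118.5, -116)
  a1 <- vapply(ll, aic_c, numeric(1), K = 3, n = 80)
  a2 <- vapply(ll + 7, aic_c, numeric(1), K = 3, n = 80)
  expect_identical(order(a1), order(a2))
})

test_that("coarsening distance bins never decreases the log-likelihood", {
  td <- tiny_dataset(n_transects = 30, n_occasions = 1, seed = 13,
                     n_bins = 8)
  f_fine <- fit_hds(td$data, ~1, ~1, "halfnorm")
  dc <- td$data
  dc$y <- dc$y[, c(TRUE, FALSE)] + dc$y[, c(FALSE, TRUE)]
  dc$bins <- dc$bins[seq(1, 9, 2)]
  f_coarse <- fit_hds(dc, ~1, ~1, "halfnorm")
  expect_gte(f_coarse$logLik, f_fine$logLik - 1e-6)
  # with g == 1 the intercept (hence lambda-hat) is unchanged by binning
  sim <- simulate_survey(flat_design(30), NULL, ~1, beta = log(5),
                         detection = ~1, alpha = log(1e6), w = 100,
                         n_occasions = 1, seed = 14)
  d8 <- make_hds_data(sim$observations, sim$transects, NULL, "point",
                      n_bins = 8, w = 100, occasions = "occ1")
  d1 <- make_hds_data(sim$observations, sim$transects, NULL, "point",
                      n_bins = 1, w = 100, occasions = "occ1")
  f8 <- fit_hds(d8, ~1, ~1, "halfnorm", start = c(1, log(1e6)))
  f1 <- fit_hds(d1, ~1, ~1, "halfnorm", start = c(1, log(1e6)))
  expect_equal(unname(f8$beta[1]), unname(f1$beta[1]), tolerance = 1e-4)
})

test_that("density conversion uses the covered-area formulae", {
  # lambda-hat = 3 at a single point station, w = 273 m
  d <- manual_data(matrix(1L, 1, 1), c(0, 273))
  f <- manual_fit(d, beta = log(3))
  dens <- estimate_density(f)
  expect_equal(dens$rows$density_km2, 3 / (pi * 0.273^2), tolerance = 1e-9)
  # doubling effort with the same per-station lambda leaves density fixed
  d2 <- manual_data(matrix(1L, 2, 1), c(0, 273))
  f2 <- manual_fit(d2, beta = log(3))
  expect_equal(estimate_density(f2)$overall$density, 3 / (pi * 0.273^2),
               tolerance = 1e-9)
  # line geometry: lambda per metre over 2 L w
  dl <- manual_data(matrix(1L, 1, 1), c(0, 60), effort = 999,
                    geometry = "line")
  fl <- manual_fit(dl, beta = log(0.01))  # 0.01 ind / m of line
  expect_equal(estimate_density(fl)$rows$density_km2,
               0.01 * 999 / (2 * 999 * 60 / 1e6), tolerance = 1e-9)
  # near-empty data: density collapses toward zero with the intercept
  dz <- manual_data(matrix(0L, 4, 2), c(0, 50, 100))
  fz <- fit_hds(dz, ~1, ~1, "halfnorm", start = c(-8, log(40)))
  expect_lt(estimate_density(fz)$overall$density, 0.1)
})

test_that("estimation bias shrinks as the number of transects grows", {
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      td <- tiny_dataset(n_transects = n, n_occasions = 1, beta0 = 1.6,
                         beta_cov = 0.5, seed = s)
      f <- fit_hds(td$data, ~x1, ~1, "halfnorm")
      abs(unname(f$beta["x1"]) - 0.5)
    }, numeric(1)))
  }
  expect_lt(bias_at(500, 1:4), bias_at(50, 1:4))
})
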