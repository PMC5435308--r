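# Shared mid-sized dataset with one informative vegetation covariate at a
# known scale plus an uninformative topographic one.
selection_fixture <- function(seed = 101, n = 80, n_occasions = 2) {
  design <- flat_design(n)
  set.seed(seed + 500)
  covs <- data.frame(veg_250 = rnorm(n), veg_1000 = rnorm(n),
                     tpi_250 = rnorm(n), tpi_1000 = rnorm(n))
  sim <- simulate_survey(design, covs,
                         abundance = ~ veg_1000 + occasion,
                         beta = c(1.6, 0.7, 0.15),
                         detection = ~1, alpha = log(40), w = 100,
                         n_occasions = n_occasions, seed = seed)
  make_hds_data(sim$observations, sim$transects, sim$covariates, "point",
                w = 100, occasions = paste0("occ", seq_len(n_occasions)))
}

test_that("univariate screening keeps the generating covariate at its scale", {
  d <- selection_fixture()
  cat <- covariate_catalog(c("veg", "tpi"),
                           c("vegetation", "topographic"))
  scr <- screen_univariate(d, cat, "abundance", "halfnorm")
  expect_true("veg" %in% scr$name)
  expect_identical(scr$column[scr$name == "veg"], "veg_1000")
  expect_true(all(scr$AICc <= attr(scr, "null_aicc")))
  # detection side returns at most one covariate
  scr_dt <- screen_univariate(d, cat, "detection", "halfnorm")
  expect_lte(nrow(scr_dt), 1L)
  # empty catalog: nothing retained, null AICc still reported
  empty <- screen_univariate(d, covariate_catalog(character(0), character(0)),
                             "abundance", "halfnorm")
  expect_identical(nrow(empty), 0L)
  expect_true(is.finite(attr(empty, "null_aicc")))
})

test_that("correlation pruning follows the greedy lower-AICc rule", {
  d <- selection_fixture()
  # identical copy: the lower-AICc member must survive
  d$frame$veg_copy <- d$frame$veg_1000
  scr <- data.frame(name = c("veg", "vegcopy"),
                    category = c("vegetation", "vegetation"),
                    column = c("veg_1000", "veg_copy"),
                    AICc = c(100, 101))
  pr <- prune_correlated(scr, d)
  expect_identical(pr$column, "veg_1000")
  # orthogonal covariates all survive
  scr2 <- data.frame(name = c("a", "b"), category = rep("vegetation", 2),
                     column = c("veg_250", "tpi_250"), AICc = c(1, 2))
  expect_identical(nrow(prune_correlated(scr2, d)), 2L)
  # chain x1-x2 correlated, x2-x3 correlated, x1-x3 not => {x1, x3};
  # built with exact correlations from a centred orthonormal basis
  set.seed(1)
  n <- nrow(d$frame)
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n), scale = FALSE)))
  d$frame$c2 <- Q[, 1]
  d$frame$c1 <- 0.8 * Q[, 1] + 0.6 * Q[, 2]
  d$frame$c3 <- 0.75 * Q[, 1] + sqrt(1 - 0.75^2) * Q[, 3]
  r12 <- abs(cor(d$frame$c1, d$frame$c2))   # 0.80
  r23 <- abs(cor(d$frame$c2, d$frame$c3))   # 0.75
  r13 <- abs(cor(d$frame$c1, d$frame$c3))   # 0.60
  expect_true(r12 > 0.7 && r23 > 0.7 && r13 < 0.7)
  scr3 <- data.frame(name = c("c1", "c2", "c3"),
                     category = rep("vegetation", 3),
                     column = c("c1", "c2", "c3"), AICc = c(1, 2, 3))
  expect_identical(prune_correlated(scr3, d)$column, c("c1", "c3"))
  # constant covariate excluded with a warning
  d$frame$flat <- 1
  scr4 <- rbind(scr3, data.frame(name = "flat", category = "vegetation",
                                 column = "flat", AICc = 0))
  expect_warning(pr4 <- prune_correlated(scr4, d), "constant")
  expect_false("flat" %in% pr4$column)
})

test_that("variance inflation factors match the closed form and prune iteratively", {
  set.seed(3)
  n <- 500
  # two-covariate case: VIF = 1/(1 - r^2); build an exact r = 0.6 pair
  x1 <- rnorm(n); x1 <- (x1 - mean(x1)) / sd(x1)
  e <- residuals(lm(rnorm(n) ~ x1)); e <- e / sd(e)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * e
  v <- check_vif(data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(v$vif), rep(1 / (1 - 0.36), 2), tolerance = 1e-6)
  expect_identical(v$keep, c("x1", "x2"))
  # orthonormal (centred) columns: all VIF 1
  q <- qr.Q(qr(scale(matrix(rnorm(n * 3), n), scale = FALSE)))
  v2 <- check_vif(as.data.frame(q))
  expect_equal(unname(v2$vif), rep(1, 3), tolerance = 1e-8)
  # one member of a near-duplicate pair gets removed, the rest survive
  v3 <- check_vif(data.frame(a = x1, b = x1 + rnorm(n, 0, 0.01),
                             c = rnorm(n)))
  expect_identical(length(v3$keep), 2L)
  expect_true("c" %in% v3$keep)
  expect_identical(sum(c("a", "b") %in% v3$keep), 1L)
  expect_gt(max(v3$vif), 100)
  # exactly collinear column is dropped before VIF computation
  expect_warning(v4 <- check_vif(data.frame(a = x1, b = 2 * x1,
                                            c = rnorm(n))),
                 "collinear")
  expect_false("b" %in% names(v4$vif))
})

test_that("the candidate grammar builds the category set and bins detection", {
  d <- selection_fixture()
  # two vegetation covariates + one topographic so Top Mix != Global
  pruned <- data.frame(
    name = c("veg", "tpi", "veg2"),
    category = c("vegetation", "topographic", "vegetation"),
    column = c("veg_1000", "tpi_250", "veg_250"), AICc = c(1, 2, 3))
  det <- data.frame(name = "veg", category = "vegetation",
                    column = "veg_250", AICc = 5)
  cand <- build_candidates(pruned, det, d)
  expect_setequal(names(cand$abundance),
                  c("Global", "Vegetation", "Topography", "Climate",
                    "Top Mix"))
  expect_setequal(all.vars(cand$abundance$`Top Mix`),
                  c("veg_1000", "tpi_250", "occasion"))
  # empty categories are flagged and collapse to occasion-only (the
  # anthropogenic and null copies deduplicate against climate)
  expect_setequal(cand$collapsed, c("Climate", "Anthropogenic"))
  expect_identical(deparse(cand$abundance$Climate), "~occasion")
  # the global model contains every other candidate's covariates
  gv <- all.vars(cand$abundance$Global)
  for (f in cand$abundance) expect_true(all(all.vars(f) %in% gv))
  # four detection candidates with the categorical column added to data
  expect_identical(length(cand$detection), 4L)
  expect_true("veg_250_cat" %in% names(cand$data$frame))
  # categorical cutpoints are equal thirds of the sampled range
  x <- d$frame$veg_250
  br <- seq(min(x), max(x), length.out = 4)
  got <- table(cand$data$frame$veg_250_cat)
  want <- table(cut(x, br, include.lowest = TRUE, labels = c("L", "M", "H")))
  expect_identical(as.vector(got), as.vector(want))
  # equal-thirds arithmetic on a [0, 0.9] range
  expect_equal(seq(0, 0.9, length.out = 4)[2:3], c(0.3, 0.6))
})

test_that("selection tables are normalized and identical models split weight", {
  d <- selection_fixture()
  f1 <- fit_hds(d, ~occasion, ~1, "halfnorm")
  f2 <- fit_hds(d, ~occasion, ~1, "halfnorm")
  f3 <- fit_hds(d, ~ veg_1000 + occasion, ~1, "halfnorm")
  tab <- hdsland:::selection_table(list(A = f1, B = f2, C = f3))
  expect_equal(sum(tab$Weight), 1, tolerance = 1e-9)
  expect_identical(tab$Delta[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  # the two identical occasion-only models carry equal weight
  wAB <- tab$Weight[tab$Model %in% c("A", "B")]
  expect_equal(wAB[1], wAB[2], tolerance = 1e-12)
  expect_identical(tab$Model[1], "C")  # the generating model wins here
  # QAICc with c-hat = 1 preserves the AICc ranking
  tabq <- hdsland:::selection_table(list(A = f1, C = f3), c_hat = 1)
  expect_identical(tabq$Model, tab$Model[tab$Model != "B"])
})

test_that("three-phase selection lands on the generating structure", {
  d <- selection_fixture(seed = 201, n = 100)
  pruned <- data.frame(
    name = c("veg", "tpi"), category = c("vegetation", "topographic"),
    column = c("veg_1000", "tpi_250"), AICc = c(1, 2))
  cand <- build_candidates(pruned, NULL, d)
  sel <- select_models(cand$data, cand, "halfnorm")
  expect_true(sel$abundance_model %in% c("Vegetation", "Global"))
  expect_equal(sum(sel$abundance_table$Weight), 1, tolerance = 1e-9)
  expect_equal(sum(sel$detection_table$Weight), 1, tolerance = 1e-9)
  expect_identical(sel$abundance_table$Delta[1], 0)
  expect_s3_class(sel$fit, "hds_fit")
  # CSV serialization of the ranking table
  p <- file.path(tempdir(), "sel.csv")
  write_selection_table(sel$abundance_table, p)
  back <- read.csv(p)
  expect_identical(names(back),
                   c("Model", "K", "AICc", "Delta_AICc", "AICc_Wt", "LL"))
  expect_equal(back$AICc, sel$abundance_table$AICc, tolerance = 1e-10)
})
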