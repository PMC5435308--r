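test_that("detection functions match their closed forms and limits", {
  hn <- detection_spec("halfnorm", 50)
  expect_equal(g_detect(0, hn), 1)
  expect_equal(g_detect(50, hn), exp(-0.5), tolerance = 1e-12)
  hz <- detection_spec("hazard", 50, shape = 3)
  expect_equal(g_detect(0, hz), 1)
  expect_lt(g_detect(5000, hz), 1e-6)
  expect_equal(g_detect(1e-12, hz), 1)
  expect_true(all(g_detect(seq(0, 300, 10), hz) >= 0 &
                  g_detect(seq(0, 300, 10), hz) <= 1))
  expect_error(g_detect(-1, hn), "distance")
  expect_error(detection_spec("halfnorm", -2), "sigma")
  expect_error(detection_spec("hazard", 50), "shape")
})

test_that("point-transect half-normal cell probability matches the analytic integral", {
  for (sigma in c(20, 50, 120, 400)) for (w in c(60, 150, 273)) {
    p <- sum(cell_probabilities(detection_spec("halfnorm", sigma),
                                distance_bins(c(0, w)), "point"))
    closed <- (2 * sigma^2 / w^2) * (1 - exp(-w^2 / (2 * sigma^2)))
    expect_equal(p, closed, tolerance = 1e-8)
  }
})

test_that("line-transect cell probability matches brute-force Riemann quadrature", {
  sigma <- 45; w <- 120
  spec <- detection_spec("halfnorm", sigma)
  p <- sum(cell_probabilities(spec, distance_bins(c(0, w)), "line"))
  brute <- riemann_p(function(x) exp(-x^2 / (2 * sigma^2)) / w, 0, w)
  expect_equal(p, brute, tolerance = 1e-6)
  hzs <- detection_spec("hazard", 45, shape = 2.5)
  ph <- sum(cell_probabilities(hzs, distance_bins(c(0, w)), "line"))
  bruteh <- riemann_p(function(x) g_detect(x, hzs) / w, 0, w)
  expect_equal(ph, bruteh, tolerance = 1e-6)
})

test_that("perfect detection recovers the geometric area density", {
  bins <- distance_bins(c(0, 30, 80, 150))
  for (geom in c("point", "line")) {
    p <- cell_probabilities(detection_spec("halfnorm", 1e8), bins, geom)
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  # point geometry with g == 1 gives annulus-area fractions
  p <- cell_probabilities(detection_spec("halfnorm", 1e8), bins, "point")
  w <- 150; c2 <- c(0, 30, 80, 150)^2
  expect_equal(p, diff(c2) / w^2, tolerance = 1e-6)
})

test_that("cell probabilities are a proper sub-distribution, stable to bin refinement", {
  spec <- detection_spec("hazard", 40, shape = 2)
  coarse <- distance_bins(c(0, 50, 100))
  fine <- distance_bins(c(0, 20, 50, 70, 100))
  for (geom in c("point", "line")) {
    pc <- cell_probabilities(spec, coarse, geom)
    pf <- cell_probabilities(spec, fine, geom)
    expect_true(all(pc >= 0) && sum(pc) <= 1 + 1e-12)
    expect_equal(sum(pc), sum(pf), tolerance = 1e-10)
    expect_equal(pc, c(sum(pf[1:2]), sum(pf[3:4])), tolerance = 1e-10)
  }
})

test_that("average detection probability behaves across the sigma grid", {
  w <- 100
  expect_equal(average_p(detection_spec("halfnorm", 1e9), w, "line"), 1,
               tolerance = 1e-8)
  # sigma = w closed form for point geometry
  expect_equal(average_p(detection_spec("halfnorm", w), w, "point"),
               2 * (1 - exp(-0.5)), tolerance = 1e-8)
  # strictly increasing in sigma, both geometries and families
  sig <- c(20, 40, 80, 160)
  for (geom in c("point", "line")) {
    ps <- vapply(sig, function(s)
      average_p(detection_spec("halfnorm", s), w, geom), numeric(1))
    expect_true(all(diff(ps) > 0))
    ph <- vapply(sig, function(s)
      average_p(detection_spec("hazard", s, shape = 2.3), w, geom),
      numeric(1))
    expect_true(all(diff(ph) > 0))
  }
})

test_that("hazard-rate with large shape approaches a step at sigma", {
  w <- 100; sigma <- 60
  p <- average_p(detection_spec("hazard", sigma, shape = 150), w, "point")
  # step-function limit: detect everything inside sigma, nothing beyond
  expect_equal(p, sigma^2 / w^2, tolerance = 0.02)
  p2 <- average_p(detection_spec("hazard", 150, shape = 150), w, "point")
  expect_equal(p2, 1, tolerance = 0.02)
})

test_that("the fast likelihood quadrature agrees with the adaptive integrator", {
  cut <- seq(0, 130, length.out = 11)
  for (geom in c("point", "line")) {
    P <- hdsland:::.pi_matrix(c(35, 70), "halfnorm", cut, geom)$P
    for (k in 1:2) {
      ref <- cell_probabilities(detection_spec("halfnorm", c(35, 70)[k]),
                                distance_bins(cut), geom)
      expect_equal(unname(P[k, ]), ref, tolerance = 1e-8)
    }
    Ph <- hdsland:::.pi_matrix(c(35, 70), "hazard", cut, geom,
                               shape = 2.2)$P
    for (k in 1:2) {
      ref <- cell_probabilities(detection_spec("hazard", c(35, 70)[k], 2.2),
                                distance_bins(cut), geom)
      expect_equal(unname(Ph[k, ]), ref, tolerance = 1e-6)
    }
  }
})

test_that("bin cutpoints are validated", {
  expect_error(distance_bins(c(10, 20)), "start at 0")
  expect_error(distance_bins(c(0, 20, 20)), "increasing")
  expect_identical(attr(distance_bins(c(0, 50, 90)), "w"), 90)
})
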