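# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force and kept independent of the
# package's own computational paths.

# Brute-force circular focal mean: enumerate every cell within the radius.
focal_mean_bruteforce <- function(values, resolution, radius) {
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is.finite(values[i, j])) next
    s <- 0; n <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      if (((a - i)^2 + (b - j)^2) * resolution^2 <= radius^2 &&
          is.finite(values[a, b])) {
        s <- s + values[a, b]; n <- n + 1
      }
    }
    out[i, j] <- s / n
  }
  out
}

# Brute-force marginal likelihood of one transect-occasion: sum over the
# latent abundance N of Poisson(N; lambda) * Multinomial(y; N, pi).
row_loglik_enumerate <- function(y, lambda, pi_j, N_max = 500L) {
  y_tot <- sum(y)
  p0 <- 1 - sum(pi_j)
  total <- 0
  for (N in y_tot:N_max) {
    lmult <- lgamma(N + 1) - sum(lgamma(y + 1)) - lgamma(N - y_tot + 1) +
      sum(y * log(pi_j)) + (N - y_tot) * log(max(p0, .Machine$double.xmin))
    if (p0 == 0 && N > y_tot) next
    total <- total + exp(stats::dpois(N, lambda, log = TRUE) + lmult)
  }
  log(total)
}

# Riemann-sum quadrature of a detection function over [a, b] (midpoint
# rule at n nodes); the dumb cross-check for cell probabilities.
riemann_p <- function(g, a, b, n = 1e6) {
  x <- seq(a, b, length.out = n + 1)
  mid <- (x[-1] + x[-length(x)]) / 2
  sum(g(mid)) * (b - a) / n
}

# Lag-1 spatial autocorrelation (row direction) of a raster matrix.
lag1_cor <- function(values) {
  stats::cor(as.vector(values[-1, ]), as.vector(values[-nrow(values), ]))
}

# Flat point-transect design: n independent single-station transects.
flat_design <- function(n) {
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             transect_id = sprintf("T%03d", seq_len(n)),
             type = "point", effort = 1, x = 0, y = 0,
             stringsAsFactors = FALSE)
}

# Minimal hand-built dataset: one geometry, explicit counts and bins.
manual_data <- function(y, bins, effort = rep(1, nrow(y)),
                        geometry = "point", occ = NULL, site = NULL) {
  n <- nrow(y)
  if (is.null(occ)) occ <- factor(rep("occ1", n))
  if (is.null(site)) site <- sprintf("S%03d", seq_len(n))
  structure(list(y = y, bins = bins, w = bins[length(bins)],
                 geometry = geometry, effort = effort,
                 frame = data.frame(occasion = occ,
                                    transect_id = sprintf("T%03d", seq_len(n)),
                                    site_id = site),
                 n_dropped = 0L),
            class = "hds_data")
}

# Hand-assembled fit object (perfect detection by default), for exercising
# the density conversion without an optimizer in the way.
manual_fit <- function(data, beta, alpha = log(1e8), family = "halfnorm") {
  K <- length(beta) + length(alpha)
  structure(list(beta = stats::setNames(beta, c("(Intercept)",
                   paste0("b", seq_len(max(length(beta) - 1, 0))))[
                     seq_along(beta)]),
                 alpha = stats::setNames(alpha, "(Intercept)"), log_b = NULL,
                 logLik = 0, K = K, n = nrow(data$y), AICc = NA,
                 vcov = diag(0, K), convergence = 0L, abundance = ~1,
                 detection = ~1, family = family, nodes = 25L, data = data),
            class = "hds_fit")
}

# Small simulated dataset + truth, ready for fitting.
tiny_dataset <- function(n_transects = 50, n_occasions = 2, beta0 = 1.5,
                         beta_cov = numeric(0), sigma = 40, w = 100,
                         seed = 1, n_bins = 10, family = "halfnorm",
                         shape = NULL, mean_group_size = 1,
                         occ_effects = NULL) {
  design <- flat_design(n_transects)
  ncov <- length(beta_cov)
  covs <- NULL
  ab <- ~occasion
  if (ncov > 0) {
    set.seed(seed + 7000)
    covs <- as.data.frame(matrix(rnorm(n_transects * ncov), n_transects,
                                 dimnames = list(NULL, paste0("x", 1:ncov))))
    ab <- as.formula(paste("~", paste(colnames(covs), collapse = "+"),
                           "+ occasion"))
  }
  if (n_occasions == 1) ab <- if (ncov > 0)
    as.formula(paste("~", paste(colnames(covs), collapse = "+"))) else ~1
  if (is.null(occ_effects)) occ_effects <- rep(0, max(n_occasions - 1, 0))
  beta <- c(beta0, beta_cov, if (n_occasions > 1) occ_effects)
  sim <- simulate_survey(design, covs, abundance = ab, beta = beta,
                         detection = ~1, alpha = log(sigma),
                         family = family, shape = shape, w = w,
                         n_occasions = n_occasions,
                         mean_group_size = mean_group_size, seed = seed)
  d <- make_hds_data(sim$observations, sim$transects, sim$covariates,
                     geometry = "point", n_bins = n_bins, w = w,
                     occasions = paste0("occ", seq_len(n_occasions)))
  list(data = d, sim = sim, abundance = ab, beta = beta)
}
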