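#' Freeman-Tukey fit statistic
#'
#' The variance-stabilized discrepancy for counts,
#' `SSE = sum (sqrt(y) - sqrt(yhat))^2`, additive over cells and invariant
#' to their ordering.
#'
#' @param y observed counts.
#' @param yhat fitted expectations (same shape, >= 0).
#' @return Scalar SSE.
#' @export
freeman_tukey <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have the same shape", call. = FALSE)
  if (any(y < 0) || any(yhat < 0))
    stop("counts and expectations must be non-negative", call. = FALSE)
  sum((sqrt(y) - sqrt(yhat))^2)
}

# Fitted cell expectations mu_ij = lambda_i pi_ij for an hds_fit.
fitted_cells <- function(fit) {
  data <- fit$data
  m <- .hds_model(data, fit$abundance, fit$detection, fit$family)
  lambda <- exp(drop(m$X %*% fit$beta) + log(data$effort))
  sigma <- exp(drop(m$V %*% fit$alpha))
  shape <- if (fit$family == "hazard") exp(fit$log_b) else NULL
  lambda * .pi_matrix(sigma, fit$family, data$bins, data$geometry, shape,
                      nodes = fit$nodes)$P
}

#' Parametric-bootstrap goodness of fit with over-dispersion estimate
#'
#' Simulates `B` datasets from the fitted marginal model
#' (`y*_ij ~ Poisson(mu_hat_ij)`), refits each, and compares the observed
#' Freeman-Tukey SSE with the bootstrap SSE distribution. The p-value uses
#' the `(1 + #{SSE* >= SSE_obs}) / (B + 1)` convention (never exactly 0);
#' the over-dispersion factor is `c_hat = SSE_obs / mean(SSE*)`. A model
#' fits when its SSE does not differ significantly from the bootstrap
#' distribution. Refits start from the original optimum for speed; more
#' than 10% refit failures aborts.
#'
#' @param fit a converged `hds_fit`.
#' @param B number of bootstrap datasets (the study default is 1000).
#' @param seed integer seed.
#' @return An object of class `gof_result`: list with `sse_obs`,
#'   `sse_boot`, `p_value`, `c_hat`, `B`.
#' @export
parametric_bootstrap_gof <- function(fit, B = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "hds_fit"), B >= 2)
  data <- fit$data
  mu <- fitted_cells(fit)
  sse_obs <- freeman_tukey(data$y, mu)
  par0 <- c(fit$beta, fit$alpha, fit$log_b)
  local_seed(seed)
  sse_boot <- rep(NA_real_, B)
  fails <- 0L
  for (b in seq_len(B)) {
    yb <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    db <- data
    db$y <- yb
    fb <- tryCatch(
      fit_hds(db, fit$abundance, fit$detection, fit$family,
              start = unname(par0), nodes = fit$nodes),
      error = function(e) NULL)
    if (is.null(fb)) { fails <- fails + 1L; next }
    sse_boot[b] <- freeman_tukey(yb, fitted_cells(fb))
  }
  if (fails > 0.1 * B)
    stop(sprintf("parametric bootstrap: %d/%d refits failed", fails, B),
         call. = FALSE)
  sse_boot <- sse_boot[!is.na(sse_boot)]
  p <- (1 + sum(sse_boot >= sse_obs)) / (length(sse_boot) + 1)
  c_hat <- if (sse_obs == 0) 1 else sse_obs / mean(sse_boot)
  structure(list(sse_obs = sse_obs, sse_boot = sse_boot, p_value = p,
                 c_hat = c_hat, B = B, n_failed = fails),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "<gof_result> Freeman-Tukey SSE = %.3f, bootstrap B = %d\n", x$sse_obs,
    x$B))
  cat(sprintf("  p = %.4f, c-hat = %.3f\n", x$p_value, x$c_hat))
  invisible(x)
}

#' Inflate standard errors for over-dispersion
#'
#' Scales the coefficient covariance by `c_hat` (so every SE is multiplied
#' by `sqrt(c_hat)`); `c_hat < 1` is treated as 1 (no deflation). The
#' returned fit also records `c_hat` so downstream intervals and
#' predictions use the widened covariance.
#'
#' @param fit an `hds_fit`.
#' @param c_hat over-dispersion factor.
#' @return The adjusted `hds_fit`.
#' @export
inflate_se <- function(fit, c_hat) {
  stopifnot(inherits(fit, "hds_fit"))
  c_hat <- max(c_hat, 1)
  fit$vcov <- fit$vcov * c_hat
  fit$c_hat <- c_hat
  fit
}

#' Nonparametric (site-level) bootstrap of occasion densities
#'
#' Resamples sites with replacement (all transect-occasion rows of a
#' resampled site move together, preserving within-site dependence),
#' refits the model, and recomputes the per-occasion mean density. Used
#' for occasion-specific density standard errors under over-dispersion.
#'
#' @param fit a converged `hds_fit`.
#' @param R bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @return `data.frame` with one row per occasion: bootstrap mean and SD
#'   of mean density (individuals/km2), plus the plug-in estimate.
#' @export
nonparametric_bootstrap_density <- function(fit, R = 200L, seed = 1L) {
  stopifnot(inherits(fit, "hds_fit"), R >= 2)
  data <- fit$data
  sites <- unique(data$frame$site_id)
  par0 <- unname(c(fit$beta, fit$alpha, fit$log_b))
  occ_levels <- levels(data$frame$occasion)
  plug <- estimate_density(fit)$by_occasion
  local_seed(seed)
  draws <- matrix(NA_real_, R, length(occ_levels))
  for (r in seq_len(R)) {
    pick <- sample(sites, length(sites), replace = TRUE)
    idx <- unlist(lapply(pick, function(s) which(data$frame$site_id == s)))
    db <- data
    db$y <- data$y[idx, , drop = FALSE]
    db$effort <- data$effort[idx]
    db$frame <- data$frame[idx, , drop = FALSE]
    fb <- tryCatch(
      fit_hds(db, fit$abundance, fit$detection, fit$family, start = par0,
              nodes = fit$nodes),
      error = function(e) NULL)
    if (is.null(fb)) next
    draws[r, ] <- estimate_density(fb)$by_occasion$density
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 0.9 * R)
    stop("nonparametric bootstrap: too many refit failures", call. = FALSE)
  data.frame(occasion = occ_levels,
             density = plug$density,
             boot_mean = colMeans(draws[ok, , drop = FALSE]),
             boot_se = apply(draws[ok, , drop = FALSE], 2, stats::sd),
             row.names = NULL)
}
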