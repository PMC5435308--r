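# Build design matrices and parameter packing for an HDS model.
.hds_model <- function(data, abundance, detection, family) {
  X <- stats::model.matrix(abundance, data$frame)
  V <- stats::model.matrix(detection, data$frame)
  if (qr(X)$rank < ncol(X))
    stop("abundance design matrix is rank-deficient", call. = FALSE)
  if (qr(V)$rank < ncol(V))
    stop("detection design matrix is rank-deficient", call. = FALSE)
  list(X = X, V = V, family = family,
       n_par = ncol(X) + ncol(V) + (family == "hazard"))
}

.unpack <- function(par, m) {
  nb <- ncol(m$X); na <- ncol(m$V)
  list(beta = par[seq_len(nb)],
       alpha = par[nb + seq_len(na)],
       log_b = if (m$family == "hazard") par[nb + na + 1L] else NULL)
}

# Objective and analytic gradient. Returns large finite values on overflow
# so the optimizer can back off.
.hds_obj <- function(par, data, m, deriv = FALSE, nodes = 25L) {
  p <- .unpack(par, m)
  eta <- drop(m$X %*% p$beta) + log(data$effort)
  lsig <- drop(m$V %*% p$alpha)
  if (any(eta > 30) || any(abs(lsig) > 30))
    return(if (deriv) list(value = 1e10, grad = rep(0, length(par)))
           else 1e10)
  lambda <- exp(eta)
  sigma <- exp(lsig)
  shape <- if (m$family == "hazard") exp(p$log_b) else NULL
  pm <- .pi_matrix(sigma, m$family, data$bins, data$geometry, shape,
                   deriv = deriv, nodes = nodes)
  mu <- lambda * pm$P
  ll <- stats::dpois(data$y, mu, log = TRUE)
  if (any(!is.finite(ll)))
    return(if (deriv) list(value = 1e10, grad = rep(0, length(par)))
           else 1e10)
  nll <- -sum(ll)
  if (!deriv) return(nll)
  # gradients
  g_beta <- drop(crossprod(m$X, lambda * rowSums(pm$P) - rowSums(data$y)))
  yoverP <- ifelse(pm$P > 0, data$y / pm$P, 0)
  g_alpha <- drop(crossprod(
    m$V, lambda * rowSums(pm$dP_lsig) - rowSums(yoverP * pm$dP_lsig)))
  grad <- c(g_beta, g_alpha)
  if (m$family == "hazard") {
    g_b <- sum(lambda * rowSums(pm$dP_lb)) - sum(yoverP * pm$dP_lb)
    grad <- c(grad, g_b)
  }
  list(value = nll, grad = grad)
}

#' Negative log-likelihood of the hierarchical distance-sampling model
#'
#' The multinomial-Poisson mixture marginal: with latent transect-occasion
#' abundance `N_i ~ Poisson(lambda_i)` and detected individuals distributed
#' over distance bins with cell probabilities `pi_ij(sigma_i)`, the binned
#' counts are marginally independent Poisson,
#' `y_ij ~ Poisson(lambda_i * pi_ij)`, with `log lambda_i = X_i beta +
#' log(effort_i)` and `log sigma_i = V_i alpha`. Returns the exact negative
#' log of the product of Poisson pmfs (constants included).
#'
#' @param par packed parameter vector: `beta`, then `alpha`, then `log(b)`
#'   for the hazard family.
#' @param data an [make_hds_data()] object.
#' @param abundance,detection model formulas.
#' @param family `"halfnorm"` or `"hazard"`.
#' @return Scalar negative log-likelihood.
#' @export
hds_nll <- function(par, data, abundance = ~1, detection = ~1,
                    family = c("halfnorm", "hazard")) {
  family <- match.arg(family)
  stopifnot(inherits(data, "hds_data"))
  if (any(!is.finite(par))) stop("parameters must be finite", call. = FALSE)
  m <- .hds_model(data, abundance, detection, family)
  if (length(par) != m$n_par)
    stop(sprintf("expected %d parameters, got %d", m$n_par, length(par)),
         call. = FALSE)
  val <- .hds_obj(par, data, m)
  if (val >= 1e10) {
    # recompute to name the offending row for diagnostics
    p <- .unpack(par, m)
    eta <- drop(m$X %*% p$beta) + log(data$effort)
    bad <- which(eta > 30)[1]
    stop(sprintf("likelihood overflow (row %s)",
                 ifelse(is.na(bad), "unknown", bad)), call. = FALSE)
  }
  val
}

#' Fit a hierarchical distance-sampling model
#'
#' Maximizes the multinomial-Poisson marginal likelihood by quasi-Newton
#' (BFGS) iteration with analytic gradients. Default starting values:
#' abundance intercept at the log mean count (per unit effort), detection
#' log-sigma at the log mean observed distance, all other coefficients 0,
#' hazard log-shape at log 2. On failure the fit is retried up to three
#' times from jittered starts.
#'
#' @param data an [make_hds_data()] object.
#' @param abundance,detection formulas for log lambda and log sigma, in
#'   terms of columns of `data$frame` (e.g. `~ shrub_1000 + occasion`).
#' @param family `"halfnorm"` or `"hazard"`.
#' @param start optional numeric start vector (packed as in [hds_nll()]).
#' @param nodes quadrature nodes per panel (config knob).
#' @return An object of class `hds_fit` with elements `beta`, `alpha`,
#'   `log_b`, `logLik`, `K`, `n`, `AICc`, `vcov`, `convergence`, plus the
#'   formulas, family and a reference to `data`.
#' @export
fit_hds <- function(data, abundance = ~1, detection = ~1,
                    family = c("halfnorm", "hazard"), start = NULL,
                    nodes = 25L) {
  family <- match.arg(family)
  stopifnot(inherits(data, "hds_data"))
  m <- .hds_model(data, abundance, detection, family)
  if (is.null(start)) {
    mean_count <- mean(rowSums(data$y) / data$effort)
    b0 <- log(max(mean_count, 1e-4))
    # mean observed distance from binned counts (bin midpoints)
    mids <- (data$bins[-1] + data$bins[-length(data$bins)]) / 2
    tot <- colSums(data$y)
    dbar <- if (sum(tot) > 0) sum(mids * tot) / sum(tot) else data$w / 2
    start <- c(b0, rep(0, ncol(m$X) - 1L), log(dbar),
               rep(0, ncol(m$V) - 1L))
    if (family == "hazard") start <- c(start, log(2))
  }
  if (length(start) != m$n_par)
    stop("wrong length of 'start'", call. = FALSE)
  fn <- function(p) .hds_obj(p, data, m, nodes = nodes)
  gr <- function(p) .hds_obj(p, data, m, deriv = TRUE, nodes = nodes)$grad
  fit <- NULL
  for (attempt in 0:3) {
    st <- if (attempt == 0) start else {
      # deterministic restart jitter; leaves the caller's RNG untouched
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      set.seed(760813L + attempt)
      j <- stats::rnorm(length(start), 0, 0.3 * attempt)
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
      start + j
    }
    o <- tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && o$convergence == 0 && o$value < 1e9) { fit <- o; break }
  }
  if (is.null(fit))
    stop("fit_hds: optimizer failed to converge after restarts",
         call. = FALSE)
  # Hessian by central differences of the analytic gradient
  K <- m$n_par
  H <- matrix(NA_real_, K, K)
  h <- 1e-5 * (abs(fit$par) + 1)
  for (k in seq_len(K)) {
    e <- rep(0, K); e[k] <- h[k]
    H[, k] <- (gr(fit$par + e) - gr(fit$par - e)) / (2 * h[k])
  }
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, K, K))
  p <- .unpack(fit$par, m)
  n <- nrow(data$y)
  nms <- c(paste0("lam_", colnames(m$X)), paste0("p_", colnames(m$V)),
           if (family == "hazard") "log_shape")
  dimnames(vc) <- list(nms, nms)
  out <- list(
    beta = stats::setNames(p$beta, colnames(m$X)),
    alpha = stats::setNames(p$alpha, colnames(m$V)),
    log_b = p$log_b,
    logLik = -fit$value, K = K, n = n,
    AICc = aic_c(-fit$value, K, n),
    vcov = vc, convergence = fit$convergence,
    abundance = abundance, detection = detection, family = family,
    nodes = nodes, data = data)
  class(out) <- "hds_fit"
  out
}

#' @export
print.hds_fit <- function(x, ...) {
  cat(sprintf("<hds_fit> %s detection, logLik = %.3f, K = %d, AICc = %.3f\n",
              x$family, x$logLik, x$K, x$AICc))
  cat("abundance (log lambda):\n"); print(round(x$beta, 4))
  cat("detection (log sigma):\n"); print(round(x$alpha, 4))
  if (!is.null(x$log_b)) cat(sprintf("hazard shape b = %.4f\n", exp(x$log_b)))
  invisible(x)
}

#' @export
logLik.hds_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, class = "logLik")
}

#' @export
coef.hds_fit <- function(object, ...) {
  c(stats::setNames(object$beta, paste0("lam_", names(object$beta))),
    stats::setNames(object$alpha, paste0("p_", names(object$alpha))),
    if (!is.null(object$log_b)) c(log_shape = object$log_b))
}

#' @export
vcov.hds_fit <- function(object, ...) object$vcov

#' Coefficient table with (possibly inflated) confidence intervals
#'
#' @param fit an `hds_fit`.
#' @param level confidence level.
#' @return `data.frame` with estimate, SE, lower, upper per coefficient.
#' @export
coef_table <- function(fit, level = 0.95) {
  est <- coef(fit)
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(est), estimate = unname(est), se = se,
             lower = unname(est) - z * se, upper = unname(est) + z * se,
             row.names = NULL)
}

#' Small-sample information criteria
#'
#' `AICc = -2 logLik + 2K + 2K(K+1)/(n-K-1)`. The quasi-likelihood variant
#' divides the log-likelihood by the over-dispersion factor c-hat and
#' counts c-hat as one extra parameter: `QAICc = -2 logLik / c_hat + 2K' +
#' 2K'(K'+1)/(n-K'-1)` with `K' = K + 1`.
#'
#' @param logLik maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n sample size (transect-occasion rows).
#' @param c_hat over-dispersion factor (>= 1 sensible).
#' @return Scalar criterion value.
#' @export
aic_c <- function(logLik, K, n) {
  if (n <= K + 1) stop("AICc requires n > K + 1", call. = FALSE)
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' @rdname aic_c
#' @export
qaic_c <- function(logLik, K, n, c_hat) {
  Kp <- K + 1
  if (n <= Kp + 1) stop("QAICc requires n > K + 2", call. = FALSE)
  if (c_hat < 1) c_hat <- 1
  -2 * logLik / c_hat + 2 * Kp + 2 * Kp * (Kp + 1) / (n - Kp - 1)
}

#' Density estimates from a fitted model
#'
#' Converts fitted transect-occasion abundance to density in
#' individuals/km2 by dividing by the covered area (`effort * pi w^2` per
#' point transect, `2 L w` per line). Standard errors come from the delta
#' method on the abundance coefficients; supplying `c_hat > 1` inflates
#' them by `sqrt(c_hat)`.
#'
#' @param fit an `hds_fit`.
#' @param c_hat optional over-dispersion factor for SE inflation.
#' @param level confidence level for the intervals.
#' @return list with `rows` (per transect-occasion density), `by_occasion`
#'   (mean density, SE, CI per occasion) and `overall` (grand mean row).
#' @export
estimate_density <- function(fit, c_hat = NULL, level = 0.95) {
  data <- fit$data
  m <- .hds_model(data, fit$abundance, fit$detection, fit$family)
  eta <- drop(m$X %*% fit$beta) + log(data$effort)
  lambda <- exp(eta)
  area_km2 <- covered_area(data$effort, data$geometry, data$w) / 1e6
  dens <- lambda / area_km2
  vc_b <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta), drop = FALSE]
  infl <- if (!is.null(c_hat) && c_hat > 1) c_hat else 1
  vc_b <- vc_b * infl
  occ <- data$frame$occasion
  z <- stats::qnorm(1 - (1 - level) / 2)
  one_group <- function(idx) {
    md <- mean(dens[idx])
    # d mean / d beta = mean_i dens_i * x_i
    a <- colMeans(m$X[idx, , drop = FALSE] * dens[idx])
    q <- drop(a %*% vc_b %*% a)
    # a singular information matrix (e.g. all-zero counts) gives no SE
    se <- if (is.finite(q) && q >= 0) sqrt(q) else NA_real_
    c(density = md, se = se, lower = max(md - z * se, 0), upper = md + z * se)
  }
  by_occ <- t(vapply(levels(occ), function(l) one_group(occ == l),
                     numeric(4)))
  overall <- one_group(seq_along(dens))
  list(rows = data.frame(data$frame[c("transect_id", "site_id")],
                         occasion = occ, lambda = lambda,
                         density_km2 = dens, row.names = NULL),
       by_occasion = data.frame(occasion = levels(occ), by_occ,
                                row.names = NULL),
       overall = data.frame(occasion = "all", t(overall), row.names = NULL))
}
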