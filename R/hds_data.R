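#' Quantile truncation of distance observations
#'
#' Drops the farthest observations to avoid a long-tailed distance
#' distribution before fitting: 10% for point-transect data and 5% for
#' line-transect data by default. The number dropped is
#' `ceiling(fraction * n)`; observations tied with the largest retained
#' distance are kept (deterministic, conservative), and the truncation
#' distance w is the maximum retained distance.
#'
#' @param distances numeric vector of observed distances (m), non-empty.
#' @param geometry `"point"` or `"line"` (sets the default fraction).
#' @param fraction override the truncation fraction (in `(0, 0.5)`).
#' @return list with `keep` (logical index into `distances`) and `w`.
#' @export
truncate_distances <- function(distances, geometry = c("point", "line"),
                               fraction = NULL) {
  geometry <- match.arg(geometry)
  if (length(distances) == 0)
    stop("no observations to truncate", call. = FALSE)
  if (is.null(fraction)) fraction <- if (geometry == "point") 0.10 else 0.05
  if (fraction <= 0 || fraction >= 0.5)
    stop("'fraction' must be in (0, 0.5)", call. = FALSE)
  n <- length(distances)
  n_drop <- ceiling(fraction * n)
  srt <- sort(distances)
  cut <- srt[n - n_drop]          # largest retained order statistic
  keep <- distances <= cut
  list(keep = keep, w = max(distances[keep]))
}

#' Expand grouped observations to individuals
#'
#' Each detected group of size k becomes k individual records at the
#' group's distance; total individuals are conserved. Cluster size is not
#' modelled further downstream.
#'
#' @param observations `data.frame` with at least `distance_m` and
#'   `group_size` columns.
#' @return The expanded `data.frame` with `group_size` column set to 1.
#' @export
expand_groups <- function(observations) {
  gs <- observations$group_size
  if (is.null(gs)) gs <- rep(1L, nrow(observations))
  if (any(gs < 1)) stop("group sizes must be >= 1", call. = FALSE)
  out <- observations[rep(seq_len(nrow(observations)), times = gs), ,
                      drop = FALSE]
  out$group_size <- rep(1L, nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble a binned survey dataset for fitting
#'
#' Expands groups to individuals, applies quantile truncation, bins the
#' retained distances into `n_bins` equal-width distance classes on
#' `[0, w]`, and lays the counts out as a transect-occasion by bin matrix
#' (all transect-occasion combinations present, including zero rows).
#' Transect-level covariates are replicated across occasions and stored
#' alongside an `occasion` factor (first occasion = reference level).
#'
#' @param observations detected groups (`transect_id`, `occasion`,
#'   `distance_m`, `group_size`).
#' @param transects transect table (`transect_id`, `type`, `effort`,
#'   optionally `site_id`).
#' @param covariates optional transect-level covariate `data.frame`
#'   aligned with `transects` rows.
#' @param geometry `"point"` or `"line"`; only transects of this type are
#'   used.
#' @param n_bins number of equal-width distance bins (default 10).
#' @param w truncation distance; if `NULL`, computed by
#'   [truncate_distances()] with the geometry default fraction.
#' @param truncation optional truncation fraction override.
#' @param occasions optional character vector fixing the occasion levels.
#' @return An object of class `hds_data`: list with count matrix `y`,
#'   `bins` cutpoints, `w`, `geometry`, `effort`, `frame` (covariates +
#'   `occasion` + ids), and `n_dropped` (observations truncated away).
#' @export
make_hds_data <- function(observations, transects, covariates = NULL,
                          geometry = c("point", "line"), n_bins = 10L,
                          w = NULL, truncation = NULL, occasions = NULL) {
  geometry <- match.arg(geometry)
  keep_tr <- transects$type == geometry
  tr <- transects[keep_tr, , drop = FALSE]
  if (nrow(tr) == 0) stop("no transects of the requested geometry", call. = FALSE)
  cv <- if (is.null(covariates)) NULL else covariates[keep_tr, , drop = FALSE]
  obs <- observations[observations$transect_id %in% tr$transect_id, ,
                      drop = FALSE]
  obs <- expand_groups(obs)
  n_dropped <- 0L
  if (is.null(w)) {
    if (nrow(obs) == 0)
      stop("cannot infer 'w' from zero observations; supply it", call. = FALSE)
    tct <- truncate_distances(obs$distance_m, geometry, truncation)
    n_dropped <- sum(!tct$keep)
    obs <- obs[tct$keep, , drop = FALSE]
    w <- tct$w
  } else {
    keep <- obs$distance_m <= w
    n_dropped <- sum(!keep)
    obs <- obs[keep, , drop = FALSE]
  }
  if (is.null(occasions)) occasions <- sort(unique(obs$occasion))
  if (length(occasions) == 0) occasions <- "occ1"
  occ <- factor(occasions, levels = occasions)
  cut <- seq(0, w, length.out = n_bins + 1L)
  n_tr <- nrow(tr)
  n_row <- n_tr * length(occ)
  y <- matrix(0L, n_row, n_bins)
  row_tr <- rep(seq_len(n_tr), times = length(occ))
  row_occ <- rep(seq_along(occ), each = n_tr)
  if (nrow(obs) > 0) {
    i_tr <- match(obs$transect_id, tr$transect_id)
    i_occ <- match(obs$occasion, occasions)
    if (anyNA(i_occ))
      stop("observations contain occasion labels not in 'occasions'",
           call. = FALSE)
    bin <- findInterval(obs$distance_m, cut, rightmost.closed = TRUE,
                        all.inside = TRUE)
    ri <- i_tr + (i_occ - 1L) * n_tr
    for (k in seq_along(ri)) y[ri[k], bin[k]] <- y[ri[k], bin[k]] + 1L
  }
  frame <- if (is.null(cv)) data.frame(row.names = seq_len(n_row))
           else cv[row_tr, , drop = FALSE]
  frame$occasion <- occ[row_occ]
  frame$transect_id <- tr$transect_id[row_tr]
  frame$site_id <- if ("site_id" %in% names(tr)) tr$site_id[row_tr]
                   else tr$transect_id[row_tr]
  rownames(frame) <- NULL
  structure(list(y = y, bins = cut, w = w, geometry = geometry,
                 effort = tr$effort[row_tr], frame = frame,
                 n_dropped = n_dropped),
            class = "hds_data")
}

#' @export
print.hds_data <- function(x, ...) {
  cat(sprintf(
    "<hds_data> %s geometry: %d transect-occasions x %d bins, w = %.4g m\n",
    x$geometry, nrow(x$y), ncol(x$y), x$w))
  cat(sprintf("  %d individuals retained (%d truncated), %d occasions\n",
              sum(x$y), x$n_dropped, nlevels(x$frame$occasion)))
  invisible(x)
}
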