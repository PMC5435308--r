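#' Nested transect survey design
#'
#' Builds the nested survey layout used for sciurid/leporid sampling: each
#' site carries `lines_per_site` line transects, and along each line
#' `stations_per_line` point-count stations spaced `station_spacing` metres
#' apart. Sites are placed uniformly at random (with a margin) inside the
#' given planar extent and each line gets a random orientation, so transect
#' coordinates can be used to sample covariate landscapes.
#'
#' @param n_sites number of survey sites.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` of the study plane (m).
#' @param lines_per_site line transects per site (default 6).
#' @param stations_per_line point stations per line (default 4).
#' @param station_spacing spacing between stations along a line, metres
#'   (default 333).
#' @param seed integer seed.
#' @return A `data.frame` with one row per transect (both the line rows and
#'   their point stations): `site_id`, `transect_id`, `type` ("point" or
#'   "line"), `effort` (stations for points, length in m for lines), `x`,
#'   `y` (centroid coordinates).
#' @export
make_survey_design <- function(n_sites, extent = c(0, 10000, 0, 10000),
                               lines_per_site = 6L, stations_per_line = 4L,
                               station_spacing = 333, seed = 1L) {
  if (n_sites < 1) stop("'n_sites' must be >= 1", call. = FALSE)
  local_seed(seed)
  L <- station_spacing * (stations_per_line - 1L)
  jit <- station_spacing / 2
  margin <- L / 2 + jit + 1
  rows <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    cx <- stats::runif(1, extent[1] + margin, extent[2] - margin)
    cy <- stats::runif(1, extent[3] + margin, extent[4] - margin)
    site <- sprintf("S%03d", s)
    out <- list()
    for (l in seq_len(lines_per_site)) {
      th <- stats::runif(1, 0, pi)
      # line centred on a jittered offset from the site centre
      ox <- cx + stats::runif(1, -jit, jit)
      oy <- cy + stats::runif(1, -jit, jit)
      t_along <- seq(-L / 2, L / 2, length.out = stations_per_line)
      px <- ox + t_along * cos(th)
      py <- oy + t_along * sin(th)
      out[[length(out) + 1L]] <- data.frame(
        site_id = site,
        transect_id = sprintf("%s_L%d", site, l),
        type = "line", effort = L, x = ox, y = oy,
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        site_id = site,
        transect_id = sprintf("%s_L%d_P%d", site, l, seq_len(stations_per_line)),
        type = "point", effort = 1, x = px, y = py,
        stringsAsFactors = FALSE)
    }
    rows[[s]] <- do.call(rbind, out)
  }
  do.call(rbind, rows)
}

#' Sample focal-scale covariates at transect locations
#'
#' Extracts each (typically focal-mean) covariate raster at the transect
#' centroids, returning the site-covariate table used both to simulate and
#' to fit. Raster list names become column names.
#'
#' @param rasters named list of [land_raster] layers.
#' @param design a design `data.frame` from [make_survey_design()].
#' @return `data.frame` with one row per design row and one column per
#'   raster.
#' @export
sample_site_covariates <- function(rasters, design) {
  stopifnot(is.list(rasters), length(names(rasters)) == length(rasters))
  out <- lapply(rasters, extract_at, x = design$x, y = design$y)
  as.data.frame(out, optional = TRUE)
}

#' Simulate distance-sampling observations with known truth
#'
#' Generates transect-occasion counts from the hierarchical model: latent
#' abundance `N ~ Poisson(lambda)` with `log lambda = X beta` (per occasion,
#' per unit of effort), individuals placed uniformly in the covered
#' geometry (uniform in area within radius `w` for point stations, uniform
#' in perpendicular distance for lines), clustered into groups of size
#' `1 + Poisson(mean_group_size - 1)` sharing one distance, and each group
#' detected with probability `g(distance)` under the requested family with
#' `log sigma = V alpha`. Only detected groups are recorded.
#'
#' @param design design `data.frame` (rows of one `type` are used; see
#'   `geometry`).
#' @param covariates `data.frame` of transect-level covariates aligned with
#'   `design` rows (may be NULL for intercept-only models).
#' @param abundance,detection model formulas for log lambda and log sigma;
#'   the variable `occasion` may be used and is supplied internally.
#' @param beta,alpha generating coefficients, in `model.matrix` column
#'   order for the respective formula.
#' @param family `"halfnorm"` or `"hazard"`.
#' @param shape hazard-rate exponent (required for hazard).
#' @param w maximum recorded distance, metres.
#' @param n_occasions number of sampling occasions (labelled
#'   `occ1..occK`, first level is the reference).
#' @param mean_group_size expected group size (>= 1); 1 means solitary.
#' @param geometry which design rows to survey: `"point"` or `"line"`.
#' @param seed integer seed.
#' @return list with `observations` (detected groups: `transect_id`,
#'   `occasion`, `distance_m`, `group_size`), `transects` (the design rows
#'   used), `covariates`, and `truth` (per transect-occasion `lambda`, `N`,
#'   plus the generating parameters) — truth is for recovery tests only.
#' @export
simulate_survey <- function(design, covariates = NULL, abundance = ~1,
                            detection = ~1, beta, alpha, family = "halfnorm",
                            shape = NULL, w, n_occasions = 5L,
                            mean_group_size = 1, seed = 1L,
                            geometry = c("point", "line")) {
  geometry <- match.arg(geometry)
  if (!family %in% c("halfnorm", "hazard"))
    stop("'family' must be \"halfnorm\" or \"hazard\"", call. = FALSE)
  if (family == "hazard" && (is.null(shape) || shape <= 0))
    stop("hazard family requires positive 'shape'", call. = FALSE)
  if (mean_group_size < 1)
    stop("'mean_group_size' must be >= 1", call. = FALSE)
  keep <- design$type == geometry
  if (!any(keep)) stop("no design rows of the requested geometry", call. = FALSE)
  tr <- design[keep, , drop = FALSE]
  cv <- if (is.null(covariates)) data.frame(row.names = seq_len(nrow(design)))
        else covariates
  cv <- cv[keep, , drop = FALSE]
  occ <- factor(sprintf("occ%d", seq_len(n_occasions)),
                levels = sprintf("occ%d", seq_len(n_occasions)))
  if (anyNA(cv))
    stop("covariates contain missing values (transects outside the raster?)",
         call. = FALSE)
  frame <- cv[rep(seq_len(nrow(tr)), times = n_occasions), , drop = FALSE]
  frame$occasion <- rep(occ, each = nrow(tr))
  frame$transect_id <- rep(tr$transect_id, times = n_occasions)
  X <- stats::model.matrix(abundance, frame)
  V <- stats::model.matrix(detection, frame)
  if (ncol(X) != length(beta))
    stop(sprintf("beta has %d elements but the abundance design has %d columns",
                 length(beta), ncol(X)), call. = FALSE)
  if (ncol(V) != length(alpha))
    stop(sprintf("alpha has %d elements but the detection design has %d columns",
                 length(alpha), ncol(V)), call. = FALSE)
  eta <- drop(X %*% beta)
  if (any(eta > 30)) stop("log lambda exceeds 30: lambda overflow", call. = FALSE)
  effort <- rep(tr$effort, times = n_occasions)
  lambda <- exp(eta) * effort
  sigma <- exp(drop(V %*% alpha))
  local_seed(seed)
  N <- stats::rpois(length(lambda), lambda)
  obs <- vector("list", length(N))
  for (i in seq_along(N)) {
    if (N[i] == 0) next
    # partition the N individuals into groups
    sizes <- integer(0); left <- N[i]
    while (left > 0) {
      k <- min(1L + stats::rpois(1, mean_group_size - 1), left)
      sizes <- c(sizes, k); left <- left - k
    }
    d <- if (geometry == "point") w * sqrt(stats::runif(length(sizes)))
         else stats::runif(length(sizes), 0, w)
    spec <- if (family == "halfnorm") detection_spec("halfnorm", sigma[i])
            else detection_spec("hazard", sigma[i], shape)
    det <- stats::runif(length(sizes)) < g_detect(d, spec)
    if (!any(det)) next
    obs[[i]] <- data.frame(
      transect_id = frame$transect_id[i],
      occasion = as.character(frame$occasion[i]),
      distance_m = d[det], group_size = sizes[det],
      stringsAsFactors = FALSE)
  }
  obs <- if (all(vapply(obs, is.null, logical(1)))) {
    data.frame(transect_id = character(), occasion = character(),
               distance_m = numeric(), group_size = integer())
  } else do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
  rownames(obs) <- NULL
  truth <- data.frame(transect_id = frame$transect_id,
                      occasion = as.character(frame$occasion),
                      lambda = lambda, N = N, stringsAsFactors = FALSE)
  list(observations = obs,
       transects = data.frame(tr, row.names = NULL),
       covariates = data.frame(cv, row.names = NULL),
       truth = structure(truth, beta = beta, alpha = alpha, family = family,
                         shape = shape, w = w))
}

#' Write / read a survey dataset as CSV
#'
#' The on-disk dialect is two CSV files in `dir`: `transects.csv`
#' (`site_id`, `transect_id`, `type`, `effort`, `x`, `y`, plus any covariate
#' columns) and `observations.csv` (`transect_id`, `occasion`,
#' `distance_m`, `group_size`).
#'
#' @param survey a list with `transects`, `observations` and optionally
#'   `covariates` (as returned by [simulate_survey()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- survey$transects
  if (!is.null(survey$covariates) && ncol(survey$covariates) > 0)
    tr <- cbind(tr, survey$covariates)
  # 17 significant digits so doubles survive the text round trip exactly
  fmt <- function(df) {
    df[] <- lapply(df, function(x)
      if (is.double(x)) sprintf("%.17g", x) else x)
    df
  }
  utils::write.csv(fmt(tr), file.path(dir, "transects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(survey$observations),
                   file.path(dir, "observations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "transects.csv"),
                        stringsAsFactors = FALSE)
  obs <- utils::read.csv(file.path(dir, "observations.csv"),
                         stringsAsFactors = FALSE)
  base <- c("site_id", "transect_id", "type", "effort", "x", "y")
  covn <- setdiff(names(tr), base)
  list(transects = tr[intersect(base, names(tr))],
       observations = obs,
       covariates = if (length(covn)) tr[covn] else
         data.frame(row.names = seq_len(nrow(tr))))
}
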