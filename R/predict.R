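#' Raster surface of predicted density
#'
#' Applies the fitted abundance coefficients cell-wise to co-registered
#' covariate rasters: `eta = x' beta` with the occasion factor fixed at a
#' reference occasion, `density = exp(eta) / covered-area` converted to
#' individuals/km2, and the delta-method standard error
#' `density * sqrt(x' vcov x)` (the covariance already carries any
#' over-dispersion inflation applied via [inflate_se()]). Covariate rasters
#' must be on the same standardized scale as the columns used at fitting
#' time, and should be range-constrained with [constrain_range()] first so
#' the model never extrapolates.
#'
#' @param fit an `hds_fit`.
#' @param rasters named list of [land_raster] layers, one per abundance
#'   covariate in the fitted formula (names must match the model columns).
#' @param occasion occasion level the map depicts (default: the reference,
#'   i.e. first, occasion).
#' @return An object of class `density_surface`: list with `density` and
#'   `se` rasters (individuals/km2), `occasion`, and `w`.
#' @export
predict_surface <- function(fit, rasters, occasion = NULL) {
  stopifnot(inherits(fit, "hds_fit"))
  data <- fit$data
  occ_levels <- levels(data$frame$occasion)
  if (is.null(occasion)) occasion <- occ_levels[1]
  if (!occasion %in% occ_levels)
    stop("unknown occasion level: ", occasion, call. = FALSE)
  vars <- setdiff(all.vars(fit$abundance), "occasion")
  missing <- setdiff(vars, names(rasters))
  if (length(missing))
    stop("no raster supplied for fitted covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(vars)) {
    ref <- rasters[[vars[1]]]
    dims <- vapply(rasters[vars], function(r) dim(r$values), integer(2))
    if (!all(dims == dim(ref$values)))
      stop("covariate rasters are not co-registered", call. = FALSE)
  } else {
    ref <- land_raster(matrix(0, 1, 1), data$w)
  }
  n_cell <- length(ref$values)
  frame <- as.data.frame(lapply(rasters[vars],
                                function(r) as.vector(r$values)))
  if (length(vars) == 0) frame <- data.frame(row.names = seq_len(n_cell))
  frame$occasion <- factor(occasion, levels = occ_levels)
  mf <- stats::model.frame(fit$abundance, frame,
                           na.action = stats::na.pass)
  X <- stats::model.matrix(fit$abundance, mf)
  eta <- drop(X %*% fit$beta)
  # per-unit-effort covered area: pi w^2 per station, 2 w per metre of line
  area_km2 <- covered_area(1, data$geometry, data$w) / 1e6
  dens <- exp(eta) / area_km2
  vc <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta), drop = FALSE]
  se_eta <- sqrt(rowSums((X %*% vc) * X))
  se <- dens * se_eta
  valid <- stats::complete.cases(X)
  dens[!valid] <- NA_real_; se[!valid] <- NA_real_
  shp <- dim(ref$values)
  structure(list(
    density = land_raster(matrix(dens, shp[1], shp[2]), ref$resolution,
                          ref$xll, ref$yll),
    se = land_raster(matrix(se, shp[1], shp[2]), ref$resolution,
                     ref$xll, ref$yll),
    occasion = occasion, w = data$w, geometry = data$geometry),
    class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  v <- x$density$values
  ok <- is.finite(v)
  cat(sprintf(
    "<density_surface> %d x %d cells (%s geometry, occasion %s)\n",
    nrow(v), ncol(v), x$geometry, x$occasion))
  cat(sprintf("  density (ind/km2): %.3g-%.3g, median %.3g\n",
              min(v[ok]), max(v[ok]), stats::median(v[ok])))
  invisible(x)
}

#' Write a density surface to disk
#'
#' Writes paired ESRI ASCII grids (`<prefix>_density.asc`,
#' `<prefix>_se.asc`) plus a JSON sidecar with the occasion, truncation
#' distance and geometry.
#'
#' @param surface a `density_surface`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_surface <- function(surface, dir, prefix = "surface") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asc(surface$density, file.path(dir, paste0(prefix, "_density.asc")))
  write_asc(surface$se, file.path(dir, paste0(prefix, "_se.asc")))
  jsonlite::write_json(
    list(occasion = surface$occasion, w = surface$w,
         geometry = surface$geometry),
    file.path(dir, paste0(prefix, ".json")), auto_unbox = TRUE)
  invisible(dir)
}
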