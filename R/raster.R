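#' Planar raster grid
#'
#' Minimal in-memory raster used for covariate landscapes: a numeric matrix
#' of cell values on a regular planar grid, with a cell size in metres and
#' the coordinates of the lower-left corner. Row 1 of the matrix is the
#' *top* row of the grid (ESRI ASCII convention). `NA` marks nodata cells.
#'
#' @param values numeric matrix of cell values (row 1 = northernmost row).
#' @param resolution cell size in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, resolution, xll = 0, yll = 0) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("'resolution' must be a single positive number", call. = FALSE)
  structure(
    list(values = values, resolution = as.numeric(resolution),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<land_raster> %d x %d cells, %.6g m/cell, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$resolution, x$xll, x$yll))
  ok <- is.finite(v)
  cat(sprintf("  values: mean %.4g, sd %.4g, %d nodata cells\n",
              mean(v[ok]), stats::sd(v[ok]), sum(!ok)))
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' Generate a spatially autocorrelated covariate landscape
#'
#' Simulates a Gaussian random field by convolving white noise with a
#' Gaussian kernel (FFT on a torus), then standardizes the field to mean 0
#' and standard deviation 1. `correlation_range` sets the kernel standard
#' deviation, so larger values give smoother fields with longer-range
#' autocorrelation, mimicking remotely sensed vegetation/terrain layers.
#'
#' @param n_rows,n_cols grid dimensions (each at least 8).
#' @param resolution cell size in metres.
#' @param correlation_range kernel scale in metres (>= resolution).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A standardized [land_raster].
#' @export
generate_landscape <- function(n_rows, n_cols, resolution, correlation_range,
                               seed) {
  if (n_rows < 8 || n_cols < 8)
    stop("grid must be at least 8 x 8", call. = FALSE)
  if (resolution <= 0)
    stop("'resolution' must be positive", call. = FALSE)
  if (correlation_range < resolution)
    stop("'correlation_range' must be >= resolution", call. = FALSE)
  local_seed(seed)
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  sd_cells <- correlation_range / resolution
  # wrapped squared distances from the (1,1) cell on the torus
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-outer(dr^2, dc^2, `+`) / (2 * sd_cells^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  land_raster(sm, resolution)
}

#' Circular focal mean of a raster
#'
#' Replaces each cell by the mean of all cells whose centres lie within
#' `radius` metres of that cell's centre (the cell itself included). Edge
#' cells average over the in-bounds part of the window; nodata cells are
#' excluded from every mean.
#'
#' @param raster a [land_raster].
#' @param radius window radius in metres (>= resolution).
#' @return A [land_raster] of the same shape.
#' @export
focal_mean <- function(raster, radius) {
  stopifnot(inherits(raster, "land_raster"))
  res <- raster$resolution
  if (radius < res)
    stop("'radius' must be at least one cell (resolution)", call. = FALSE)
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  r_cells <- floor(radius / res)
  off <- expand.grid(dr = -r_cells:r_cells, dc = -r_cells:r_cells)
  off <- off[(off$dr^2 + off$dc^2) * res^2 <= radius^2, , drop = FALSE]
  valid <- is.finite(v)
  v0 <- ifelse(valid, v, 0)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (i in seq_len(nrow(off))) {
    dr <- off$dr[i]; dc <- off$dc[i]
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    num[rs, cs] <- num[rs, cs] + v0[rs + dr, cs + dc]
    den[rs, cs] <- den[rs, cs] + valid[rs + dr, cs + dc]
  }
  out <- num / den
  out[den == 0 | !valid] <- NA_real_
  land_raster(out, res, raster$xll, raster$yll)
}

#' Standardize a raster
#'
#' Subtracts `mean` and divides by `sd` cell-wise, the scaling applied to
#' every covariate layer before modelling. By default the raster's own
#' statistics (over valid cells) are used.
#'
#' @param raster a [land_raster].
#' @param mean,sd centring and scaling constants; defaults computed from
#'   the raster's valid cells.
#' @return A [land_raster]; nodata cells preserved.
#' @export
standardize_raster <- function(raster, mean = NULL, sd = NULL) {
  stopifnot(inherits(raster, "land_raster"))
  v <- raster$values
  ok <- is.finite(v)
  if (is.null(mean)) mean <- base::mean(v[ok])
  if (is.null(sd)) sd <- stats::sd(v[ok])
  if (!is.finite(sd) || sd <= 0)
    stop("'sd' must be positive (constant raster cannot self-standardize)",
         call. = FALSE)
  out <- (v - mean) / sd
  out[!ok] <- NA_real_
  r <- land_raster(out, raster$resolution, raster$xll, raster$yll)
  attr(r, "center") <- mean
  attr(r, "scale") <- sd
  r
}

#' Clamp raster values to a sampled range
#'
#' Constrains covariate values outside the sampling frame to the range
#' observed within sampled areas, the guard against extrapolating a
#' log-linear density model beyond the support of the data.
#'
#' @param raster a [land_raster].
#' @param sampled_min,sampled_max closed interval to clamp into.
#' @return A [land_raster] with an attribute `n_clamped` counting changed
#'   cells.
#' @export
constrain_range <- function(raster, sampled_min, sampled_max) {
  stopifnot(inherits(raster, "land_raster"))
  if (sampled_min > sampled_max)
    stop("'sampled_min' must be <= 'sampled_max'", call. = FALSE)
  v <- raster$values
  ok <- is.finite(v)
  clamped <- ok & (v < sampled_min | v > sampled_max)
  v[ok] <- pmin(pmax(v[ok], sampled_min), sampled_max)
  out <- land_raster(v, raster$resolution, raster$xll, raster$yll)
  attr(out, "n_clamped") <- sum(clamped)
  out
}

#' Extract raster values at point coordinates
#'
#' Nearest-cell lookup in the raster's planar coordinate system.
#'
#' @param raster a [land_raster].
#' @param x,y coordinate vectors (metres, same origin as the raster).
#' @return Numeric vector of cell values (`NA` outside the grid).
#' @export
extract_at <- function(raster, x, y) {
  stopifnot(inherits(raster, "land_raster"))
  v <- raster$values
  res <- raster$resolution
  col <- floor((x - raster$xll) / res) + 1L
  # matrix row 1 is the top (northern) row
  row <- nrow(v) - floor((y - raster$yll) / res)
  ok <- col >= 1L & col <= ncol(v) & row >= 1L & row <= nrow(v)
  out <- rep(NA_real_, length(x))
  out[ok] <- v[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a [land_raster].
#' @param path output file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "land_raster"))
  v <- raster$values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.10g", raster$xll),
    sprintf("YLLCORNER %.10g", raster$yll),
    sprintf("CELLSIZE %.10g", raster$resolution),
    sprintf("NODATA_VALUE %.10g", nodata)), con)
  utils::write.table(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file.
#' @return A [land_raster].
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- toupper(kv[, 1]); val <- as.numeric(kv[, 2])
  get <- function(k) val[match(k, key)]
  nc <- as.integer(get("NCOLS")); nr <- as.integer(get("NROWS"))
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("corrupt .asc: cell count does not match header", call. = FALSE)
  v <- matrix(body, nr, nc, byrow = TRUE)
  nodata <- get("NODATA_VALUE")
  if (is.finite(nodata)) v[v == nodata] <- NA_real_
  land_raster(v, get("CELLSIZE"), get("XLLCORNER"), get("YLLCORNER"))
}

# Seed the RNG locally: restores the caller's .Random.seed on exit of the
# *calling* function, so explicit-seed functions never disturb global state.
local_seed <- function(seed, env = parent.frame()) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    substitute(assign(".Random.seed", o, envir = globalenv()), list(o = old))
  }
  do.call("on.exit", list(expr, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(seed)
}
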