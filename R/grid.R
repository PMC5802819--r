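#' Define a regular longitude-latitude analysis grid
#'
#' The grid is the shared spatial frame for every stage of the pipeline:
#' emissions are accumulated into its cells, concentrations, population and
#' meteorology live on it, and all global aggregates are area-weighted over
#' it. Cells are square in degrees; physical areas use cosine-latitude
#' weighting, so high-latitude cells weigh less in global means.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain bounds in degrees
#'   (longitude in \[-180, 180\], latitude in \[-90, 90\]).
#' @param cell_size Cell edge length in degrees; must divide both spans.
#' @return An object of class `world_grid` with fields `n_lon`, `n_lat`,
#'   cell-centre coordinate vectors `lon`, `lat`, and `cell_area_m2`
#'   (an `n_lat x n_lon` matrix).
#' @examples
#' g <- world_grid(0, 20, 40, 60, cell_size = 1)
#' g$n_lon
#' @export
world_grid <- function(lon_min = -10, lon_max = 10, lat_min = 30, lat_max = 50,
                       cell_size = 1) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (lon_max <= lon_min || lat_max <= lat_min) {
    stop("grid bounds must satisfy lon_min < lon_max and lat_min < lat_max",
         call. = FALSE)
  }
  if (lon_min < -180 || lon_max > 180 || lat_min < -90 || lat_max > 90) {
    stop("grid bounds must lie in [-180, 180] x [-90, 90]", call. = FALSE)
  }
  n_lon <- round((lon_max - lon_min) / cell_size)
  n_lat <- round((lat_max - lat_min) / cell_size)
  if (n_lon < 1 || n_lat < 1) {
    stop("grid must contain at least one cell in each direction", call. = FALSE)
  }
  if (abs(n_lon * cell_size - (lon_max - lon_min)) > 1e-9 ||
      abs(n_lat * cell_size - (lat_max - lat_min)) > 1e-9) {
    stop("`cell_size` must divide the longitude and latitude spans",
         call. = FALSE)
  }
  lon <- lon_min + (seq_len(n_lon) - 0.5) * cell_size
  lat <- lat_min + (seq_len(n_lat) - 0.5) * cell_size
  r_earth <- 6371000  # mean Earth radius, m
  dx <- r_earth * cos(lat * pi / 180) * cell_size * pi / 180
  dy <- r_earth * cell_size * pi / 180
  area <- matrix(rep(dx * dy, n_lon), nrow = n_lat, ncol = n_lon)
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         cell_size = cell_size, n_lon = n_lon, n_lat = n_lat,
         lon = lon, lat = lat, cell_area_m2 = area),
    class = "world_grid")
}

#' @export
print.world_grid <- function(x, ...) {
  cat(sprintf("<world_grid> %d x %d cells of %.3g deg, lon [%g, %g], lat [%g, %g]\n",
              x$n_lat, x$n_lon, x$cell_size,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

# Row (latitude) / column (longitude) index of points on the grid.
# Cell membership is half-open [lower, upper); points on the top/right
# domain edge fall in the last cell. Out-of-domain points get NA.
grid_index <- function(grid, lon, lat) {
  ix <- floor((lon - grid$lon_min) / grid$cell_size) + 1
  iy <- floor((lat - grid$lat_min) / grid$cell_size) + 1
  ix[lon == grid$lon_max] <- grid$n_lon
  iy[lat == grid$lat_max] <- grid$n_lat
  out <- ix < 1 | ix > grid$n_lon | iy < 1 | iy > grid$n_lat |
    is.na(lon) | is.na(lat)
  ix[out] <- NA_integer_
  iy[out] <- NA_integer_
  list(row = as.integer(iy), col = as.integer(ix))
}

# Linear cell id (column-major over the n_lat x n_lon field matrix).
grid_cell_id <- function(grid, lon, lat) {
  idx <- grid_index(grid, lon, lat)
  (idx$col - 1L) * grid$n_lat + idx$row
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")],
                   b[c("lon_min", "lon_max", "lat_min", "lat_max",
                       "cell_size")]))
}

empty_field <- function(grid, value = 0) {
  matrix(value, nrow = grid$n_lat, ncol = grid$n_lon)
}

#' Area-weighted global mean of a gridded field
#'
#' @param grid A `world_grid`.
#' @param field An `n_lat x n_lon` matrix.
#' @return Scalar mean, weighting each cell by its physical area.
#' @export
area_weighted_mean <- function(grid, field) {
  stopifnot(all(dim(field) == c(grid$n_lat, grid$n_lon)))
  sum(field * grid$cell_area_m2) / sum(grid$cell_area_m2)
}

# Spatially smooth standard-normal noise: iid N(0,1) blurred by a separable
# box kernel (length = 2*half + 1) applied a few times, then re-standardised.
# Edge handling replicates border values so variance stays roughly uniform.
smooth_noise <- function(grid, correlation_cells = 3, passes = 3) {
  z <- matrix(stats::rnorm(grid$n_lat * grid$n_lon),
              nrow = grid$n_lat, ncol = grid$n_lon)
  half <- max(1L, as.integer(round(correlation_cells)))
  for (p in seq_len(passes)) {
    z <- box_blur(z, half)
  }
  (z - mean(z)) / max(stats::sd(z), .Machine$double.eps)
}

box_blur <- function(m, half) {
  k <- 2L * half + 1L
  pad_rows <- function(x) rbind(
    x[rep(1L, half), , drop = FALSE], x,
    x[rep(nrow(x), half), , drop = FALSE])
  run_mean_cols <- function(x) {
    cs <- apply(rbind(0, x), 2, cumsum)
    (cs[(k + 1):nrow(cs), , drop = FALSE] -
        cs[1:(nrow(cs) - k), , drop = FALSE]) / k
  }
  m <- run_mean_cols(pad_rows(m))
  t(run_mean_cols(pad_rows(t(m))))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
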