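#' Generate a synthetic world: land/sea mask, countries, population
#'
#' Builds the study region every other stage consumes. The land/sea mask is a
#' threshold on smoothed Gaussian noise (procedural, no shoreline data), land
#' cells are partitioned into countries by nearest-seed assignment, and the
#' population is drawn multinomially over land cells with a coastal
#' multiplier, so the configured total is conserved exactly in integer
#' persons. Each country gets an age-cohort pair (fraction aged 30+ and
#' fraction aged 14 and under), applied uniformly within the country.
#'
#' @param seed Integer seed; the generator is a pure function of
#'   `(seed, parameters)`.
#' @param grid A `world_grid` (see [world_grid()]).
#' @param n_countries Number of countries to carve out of the land mass.
#' @param coastal_bias Population-weight multiplier for coastal land cells
#'   (land cells with at least one sea neighbour). `1` means no bias.
#' @param total_population Total persons to distribute.
#' @param land_fraction Target fraction of cells that are land.
#' @param correlation_cells Smoothing half-width (in cells) of the noise used
#'   for the mask and the population texture.
#' @return A list of class `synthetic_world` with elements `grid`,
#'   `land` (logical matrix, TRUE = land), `country_id` (integer matrix, NA at
#'   sea), `coastal` (logical matrix), `population` (integer matrix),
#'   `cohorts` (data.frame: country, frac_30plus, frac_under14).
#' @examples
#' w <- generate_world(1, world_grid(0, 10, 40, 50, 1), n_countries = 2)
#' sum(w$population)
#' @export
generate_world <- function(seed, grid, n_countries = 3, coastal_bias = 3,
                           total_population = 1e7, land_fraction = 0.35,
                           correlation_cells = 2) {
  stopifnot(inherits(grid, "world_grid"))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (n_countries < 1) stop("`n_countries` must be >= 1", call. = FALSE)
  if (coastal_bias <= 0) stop("`coastal_bias` must be > 0", call. = FALSE)
  if (land_fraction <= 0 || land_fraction >= 1) {
    stop("`land_fraction` must be in (0, 1)", call. = FALSE)
  }
  set.seed(as.integer(seed))

  z <- smooth_noise(grid, correlation_cells)
  land <- z > stats::quantile(z, 1 - land_fraction)
  if (!any(land)) land[which.max(z)] <- TRUE
  if (all(land)) land[which.min(z)] <- FALSE

  country_id <- empty_field(grid, NA_integer_)
  land_cells <- which(land)
  k <- min(n_countries, length(land_cells))
  seeds <- sample(land_cells, k)
  sr <- (seeds - 1L) %% grid$n_lat + 1L
  sc <- (seeds - 1L) %/% grid$n_lat + 1L
  lr <- (land_cells - 1L) %% grid$n_lat + 1L
  lc <- (land_cells - 1L) %/% grid$n_lat + 1L
  d2 <- outer(lr, sr, "-")^2 + outer(lc, sc, "-")^2
  country_id[land_cells] <- max.col(-d2, ties.method = "first")

  coastal <- land & has_sea_neighbour(land)

  # population texture: lognormal weights from fresh smooth noise, boosted
  # on the coast; multinomial draw conserves the configured total exactly
  w <- exp(0.8 * smooth_noise(grid, correlation_cells))
  w[!land] <- 0
  w[coastal] <- w[coastal] * coastal_bias
  population <- empty_field(grid, 0L)
  if (sum(w) > 0 && total_population > 0) {
    population[] <- as.integer(stats::rmultinom(1, round(total_population),
                                                as.vector(w)))
  }

  frac30 <- stats::runif(k, 0.35, 0.60)
  frac14 <- stats::runif(k, 0.15, pmin(0.35, 0.98 - frac30))
  cohorts <- data.frame(country = seq_len(k),
                        frac_30plus = frac30,
                        frac_under14 = frac14)

  structure(list(grid = grid, land = land, country_id = country_id,
                 coastal = coastal, population = population,
                 cohorts = cohorts),
            class = "synthetic_world")
}

has_sea_neighbour <- function(land) {
  nr <- nrow(land); nc <- ncol(land)
  sea <- !land
  pad <- matrix(TRUE, nr + 2, nc + 2)  # domain edge counts as sea
  pad[2:(nr + 1), 2:(nc + 1)] <- sea
  pad[2:(nr + 1), 1:nc] | pad[2:(nr + 1), 3:(nc + 2)] |
    pad[1:nr, 2:(nc + 1)] | pad[3:(nr + 2), 2:(nc + 1)]
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d land (%d coastal), %d countries, %s persons\n",
              x$grid$n_lat, x$grid$n_lon, sum(x$land), sum(x$coastal),
              nrow(x$cohorts), format(sum(x$population), big.mark = ",")))
  invisible(x)
}

#' Generate a synthetic vessel fleet
#'
#' Draws vessel technical attributes of the kind a ship registry would
#' provide: ship type, installed main-engine power, design speed, engine
#' class with a crankshaft speed consistent with that class (slow-speed
#' < 130 rpm, medium-speed 130-2000, high-speed >= 2000), MARPOL NOx tier,
#' base specific fuel-oil consumption (valid at 80% load) and fuel family.
#'
#' @param seed Integer seed.
#' @param n_vessels Number of vessels.
#' @return A data.frame of class `vessel_fleet`, one row per vessel.
#' @export
generate_fleet <- function(seed, n_vessels) {
  set.seed(as.integer(seed) + 211L)
  if (n_vessels == 0) {
    fleet <- data.frame(vessel_id = character(), ship_type = character(),
                        installed_power_kw = numeric(),
                        design_speed_mps = numeric(),
                        engine_class = character(), crankshaft_rpm = numeric(),
                        nox_tier = integer(), base_sfoc = numeric(),
                        fuel_family = character())
    class(fleet) <- c("vessel_fleet", "data.frame")
    return(fleet)
  }
  types <- sample(c("dry_bulk", "liquid_bulk", "unitised", "passenger",
                    "miscellaneous"),
                  n_vessels, replace = TRUE,
                  prob = c(0.3, 0.25, 0.25, 0.05, 0.15))
  eng <- sample(c("SSD", "MSD", "HSD"), n_vessels, replace = TRUE,
                prob = c(0.55, 0.40, 0.05))
  rpm <- ifelse(eng == "SSD", stats::runif(n_vessels, 60, 129),
                ifelse(eng == "MSD", stats::runif(n_vessels, 300, 1000),
                       stats::runif(n_vessels, 2000, 3000)))
  fleet <- data.frame(
    vessel_id = sprintf("V%04d", seq_len(n_vessels)),
    ship_type = types,
    installed_power_kw = round(stats::rlnorm(n_vessels, log(8000), 0.5)),
    design_speed_mps = stats::runif(n_vessels, 5, 12),
    engine_class = eng,
    crankshaft_rpm = round(rpm),
    nox_tier = sample(0:3, n_vessels, replace = TRUE,
                      prob = c(0.25, 0.35, 0.35, 0.05)),
    base_sfoc = round(stats::runif(n_vessels, 165, 210)),
    fuel_family = sample(c("HFO", "MDO_MGO"), n_vessels, replace = TRUE,
                         prob = c(0.8, 0.2)))
  class(fleet) <- c("vessel_fleet", "data.frame")
  fleet
}

#' Generate lane-concentrated synthetic ship traffic
#'
#' Emulates AIS-style motion records: vessels shuttle along shipping lanes
#' (straight corridors between two sea cells) with Gaussian cross-track
#' scatter, reporting hourly position and speed. Activity is therefore
#' concentrated along lane corridors, the structural feature the emission
#' gridding and exposure stages rely on.
#'
#' @param seed Integer seed.
#' @param world A `synthetic_world`.
#' @param n_lanes Number of lanes to lay out (ignored when `lanes` given).
#' @param n_vessels Number of vessels; records reference `V0001 ...` ids
#'   matching [generate_fleet()].
#' @param period_hours Length of the activity period; one record per vessel
#'   per hour.
#' @param lanes Optional list of lanes, each `list(lon = c(from, to),
#'   lat = c(from, to))`; endpoints must be sea cells.
#' @param corridor_sd Cross-track standard deviation in cells.
#' @param design_speed_mps Per-vessel design speeds used to scale cruise
#'   speed; recycled. Defaults to 10 m/s.
#' @return A data.frame of class `vessel_activity` with columns `vessel_id`,
#'   `timestamp` (POSIXct, UTC), `lon`, `lat`, `speed_mps`. The lane list is
#'   attached as attribute `lanes`.
#' @export
generate_traffic <- function(seed, world, n_lanes = 3, n_vessels = 50,
                             period_hours = 168, lanes = NULL,
                             corridor_sd = 0.4, design_speed_mps = 10) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(as.integer(seed) + 977L)
  grid <- world$grid

  if (is.null(lanes)) {
    lanes <- propose_lanes(world, n_lanes)
  }
  for (ln in lanes) {
    idx <- grid_index(grid, ln$lon, ln$lat)
    if (anyNA(idx$row)) {
      stop("lane endpoint outside the world grid", call. = FALSE)
    }
    onland <- world$land[cbind(idx$row, idx$col)]
    if (any(onland)) {
      stop("lane endpoints must be sea cells", call. = FALSE)
    }
  }

  if (n_vessels == 0 || length(lanes) == 0 || period_hours == 0) {
    rec <- data.frame(vessel_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(),
                      speed_mps = numeric())
    class(rec) <- c("vessel_activity", "data.frame")
    attr(rec, "lanes") <- lanes
    return(rec)
  }

  ds <- rep_len(design_speed_mps, n_vessels)
  lane_of <- sample(length(lanes), n_vessels, replace = TRUE)
  cruise <- stats::runif(n_vessels, 0.6, 0.95) * ds
  phase <- stats::runif(n_vessels)
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  hours <- seq_len(period_hours) - 1L

  n <- n_vessels * period_hours
  vid <- rep(sprintf("V%04d", seq_len(n_vessels)), each = period_hours)
  lane_i <- rep(lane_of, each = period_hours)
  # triangle-wave progress along the lane: shuttle back and forth
  prog <- (rep(phase, each = period_hours) +
             rep(cruise, each = period_hours) * rep(hours, n_vessels) *
             3600 / 2e5) %% 2
  prog <- ifelse(prog > 1, 2 - prog, prog)
  lon0 <- vapply(lanes, function(l) l$lon[1], 0)[lane_i]
  lon1 <- vapply(lanes, function(l) l$lon[2], 0)[lane_i]
  lat0 <- vapply(lanes, function(l) l$lat[1], 0)[lane_i]
  lat1 <- vapply(lanes, function(l) l$lat[2], 0)[lane_i]
  jig <- stats::rnorm(n, 0, corridor_sd * grid$cell_size)
  # cross-track unit vector
  dlon <- lon1 - lon0; dlat <- lat1 - lat0
  len <- sqrt(dlon^2 + dlat^2)
  ux <- -dlat / len; uy <- dlon / len
  lon <- clamp(lon0 + prog * dlon + jig * ux,
               grid$lon_min, grid$lon_max - 1e-9)
  lat <- clamp(lat0 + prog * dlat + jig * uy,
               grid$lat_min, grid$lat_max - 1e-9)
  # mostly cruising, occasional slow manoeuvring/hotelling
  speed <- rep(cruise, each = period_hours) *
    ifelse(stats::runif(n) < 0.08, stats::runif(n, 0, 0.2), 1)
  rec <- data.frame(vessel_id = vid,
                    timestamp = t0 + 3600 * rep(hours, n_vessels),
                    lon = lon, lat = lat, speed_mps = speed)
  class(rec) <- c("vessel_activity", "data.frame")
  attr(rec, "lanes") <- lanes
  rec
}

propose_lanes <- function(world, n_lanes) {
  grid <- world$grid
  sea_cells <- which(!world$land)
  if (length(sea_cells) < 2) stop("not enough sea to route lanes", call. = FALSE)
  lanes <- vector("list", n_lanes)
  for (i in seq_len(n_lanes)) {
    for (try in 1:200) {
      ab <- sample(sea_cells, 2)
      r <- (ab - 1L) %% grid$n_lat + 1L
      c <- (ab - 1L) %/% grid$n_lat + 1L
      if (sum((r[1] - r[2])^2 + (c[1] - c[2])^2) >=
          (0.3 * max(grid$n_lat, grid$n_lon))^2) break
    }
    lanes[[i]] <- list(lon = grid$lon[c], lat = grid$lat[r])
  }
  lanes
}

#' Generate a country incidence table
#'
#' Draws per-country baseline rates: cardiovascular and lung-cancer mortality
#' per 100,000 persons aged 30+ per year, and childhood-asthma (current
#' wheeze) cases per 100,000 persons aged 14 and under per year. A
#' configurable fraction of countries report only an age-standardised rate
#' (ASR) plus a crude:ASR ratio, exercising the conversion path; countries
#' absent from the table fall back to the mean of the present countries.
#'
#' @param seed Integer seed.
#' @param countries Integer vector of country ids.
#' @param asr_only_fraction Fraction of countries whose cardiovascular rate
#'   is supplied as ASR + ratio instead of a crude rate.
#' @return A data.frame of class `incidence_table` with columns `country`,
#'   `B_cv`, `B_lc`, `B_asthma` (all per 100,000 cohort persons per year),
#'   and for ASR-only countries `cv_asr`, `cv_asr_ratio` with `B_cv`
#'   already resolved via [asr_to_crude()].
#' @export
generate_incidence <- function(seed, countries, asr_only_fraction = 0.25) {
  set.seed(as.integer(seed) + 389L)
  k <- length(countries)
  # plausible magnitudes: CV deaths ~ 400-900, LC ~ 20-80 per 100k 30+;
  # current wheeze ~ 5,000-15,000 per 100k children
  b_cv <- stats::runif(k, 400, 900)
  b_lc <- stats::runif(k, 20, 80)
  b_as <- stats::runif(k, 5000, 15000)
  if (any(c(b_cv, b_lc, b_as) < 0)) {
    stop("generated incidence rates must be non-negative", call. = FALSE)
  }
  tab <- data.frame(country = countries, B_cv = b_cv, B_lc = b_lc,
                    B_asthma = b_as,
                    cv_asr = NA_real_, cv_asr_ratio = NA_real_)
  n_asr <- round(asr_only_fraction * k)
  if (n_asr > 0) {
    pick <- sample(k, n_asr)
    ratio <- stats::runif(n_asr, 0.9, 1.6)
    tab$cv_asr[pick] <- tab$B_cv[pick] / ratio
    tab$cv_asr_ratio[pick] <- ratio
    tab$B_cv[pick] <- asr_to_crude(tab$cv_asr[pick], ratio)
  }
  class(tab) <- c("incidence_table", "data.frame")
  tab
}

#' Look up incidence rates with a global-mean fallback
#'
#' @param table An `incidence_table`.
#' @param countries Country ids to resolve.
#' @param endpoint One of `"CV"`, `"LC"`, `"ASTHMA"`.
#' @return Numeric rates per 100,000 cohort persons per year; countries not
#'   in the table get the mean over present countries.
#' @export
incidence_rate <- function(table, countries, endpoint = c("CV", "LC", "ASTHMA")) {
  endpoint <- match.arg(endpoint)
  col <- switch(endpoint, CV = "B_cv", LC = "B_lc", ASTHMA = "B_asthma")
  m <- match(countries, table$country)
  out <- table[[col]][m]
  out[is.na(m)] <- mean(table[[col]])
  out
}

#' Generate surrogate meteorological and surface fields
#'
#' Produces the 2D fields the exposure and forcing stages need: cloud
#' fraction \[0, 1\], mean insolation (W m^-2), wind speed (m s^-1), boundary
#'-layer mixing height (m), sea-salt aerosol concentration (ug m^-3, zero
#' over land), and underlying shortwave surface albedo (dark sea, brighter
#' land). All fields are spatially smooth.
#'
#' @param seed Integer seed.
#' @param world A `synthetic_world`.
#' @param correlation_cells Smoothing half-width in cells.
#' @return A list of class `meteo_fields` of `n_lat x n_lon` matrices:
#'   `cloud_fraction`, `insolation`, `wind_speed`, `mixing_height`,
#'   `sea_salt`, `albedo`.
#' @export
generate_meteo <- function(seed, world, correlation_cells = 3) {
  stopifnot(inherits(world, "synthetic_world"))
  set.seed(as.integer(seed) + 541L)
  grid <- world$grid
  u <- function() stats::pnorm(smooth_noise(grid, correlation_cells))
  cloud <- clamp(0.15 + 0.7 * u(), 0, 1)
  insol <- 120 + 220 * u()
  wind <- 2 + 10 * u()
  hmix <- 300 + 1200 * u()
  sslt <- (2 + 13 * u())
  sslt[world$land] <- 0
  albedo <- ifelse(world$land, 0.15 + 0.25 * u(), 0.06)
  out <- list(cloud_fraction = cloud, insolation = insol, wind_speed = wind,
              mixing_height = hmix, sea_salt = sslt, albedo = albedo)
  class(out) <- "meteo_fields"
  out
}

#' Generate a long-tailed background PM2.5 field
#'
#' Background (non-shipping) PM2.5 split into a sea-salt component (from the
#' meteorology) and a terrestrial/other component with a lognormal long tail
#' over land that decays towards the open sea, so that over sea the sea-salt
#' share of background PM dominates (the 50-75% marine share regime) while
#' over land terrestrial sources dominate.
#'
#' @param seed Integer seed.
#' @param world A `synthetic_world`.
#' @param meteo A `meteo_fields` (source of the sea-salt component).
#' @return List of class `background_pm` with matrices `sslt` and `other`
#'   (ug m^-3) plus `total`.
#' @export
generate_background <- function(seed, world, meteo) {
  set.seed(as.integer(seed) + 733L)
  grid <- world$grid
  z <- smooth_noise(grid, 3)
  other <- exp(1.0 * z) * 6          # lognormal long tail
  # decay of terrestrial influence with distance from land
  dist <- distance_to_land_cells(world$land)
  other <- other * exp(-dist / 4)
  other <- other + 1.0               # hemispheric floor
  total <- other + meteo$sea_salt
  structure(list(sslt = meteo$sea_salt, other = other, total = total),
            class = "background_pm")
}

# Chebyshev-distance transform to the nearest land cell, in cells.
distance_to_land_cells <- function(land) {
  d <- matrix(ifelse(land, 0, Inf), nrow(land), ncol(land))
  nr <- nrow(d); nc <- ncol(d)
  for (pass in 1:2) {
    rows <- if (pass == 1) 1:nr else nr:1
    cols <- if (pass == 1) 1:nc else nc:1
    for (i in rows) for (j in cols) {
      if (d[i, j] > 0) {
        nb <- c(if (i > 1) d[i - 1, j], if (i < nr) d[i + 1, j],
                if (j > 1) d[i, j - 1], if (j < nc) d[i, j + 1],
                if (i > 1 && j > 1) d[i - 1, j - 1],
                if (i > 1 && j < nc) d[i - 1, j + 1],
                if (i < nr && j > 1) d[i + 1, j - 1],
                if (i < nr && j < nc) d[i + 1, j + 1])
        d[i, j] <- min(d[i, j], min(nb) + 1)
      }
    }
  }
  d[!is.finite(d)] <- max(nr, nc)
  d
}
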