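# Shared fixtures, all generated in code at test time.

tiny_grid <- function() world_grid(0, 20, 30, 50, cell_size = 1)

tiny_world <- function(seed = 11) {
  generate_world(seed, tiny_grid(), n_countries = 3, coastal_bias = 3,
                 total_population = 2e6)
}

# An all-sea world: land mass confined to one corner so lanes and open-ocean
# fleets are easy to place away from it.
open_sea_world <- function(seed = 7) {
  w <- generate_world(seed, tiny_grid(), n_countries = 2, coastal_bias = 2,
                      total_population = 1e6, land_fraction = 0.12)
  w
}

# Deterministic single-vessel fixtures for hand-checkable emission sums.
one_vessel_fleet <- function(power = 10000, design_speed = 10,
                             base_sfoc = 200, fuel = "HFO",
                             engine = "SSD", rpm = 100, tier = 1,
                             type = "dry_bulk") {
  fleet <- data.frame(vessel_id = "V0001", ship_type = type,
                      installed_power_kw = power,
                      design_speed_mps = design_speed,
                      engine_class = engine, crankshaft_rpm = rpm,
                      nox_tier = tier, base_sfoc = base_sfoc,
                      fuel_family = fuel)
  class(fleet) <- c("vessel_fleet", "data.frame")
  fleet
}

records_at <- function(lon, lat, speed, n = length(lon),
                       vessel_id = "V0001") {
  rec <- data.frame(vessel_id = rep_len(vessel_id, n),
                    timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                      3600 * (seq_len(n) - 1),
                    lon = rep_len(lon, n), lat = rep_len(lat, n),
                    speed_mps = rep_len(speed, n))
  class(rec) <- c("vessel_activity", "data.frame")
  rec
}

# Independent per-record accumulation oracle: scalar loop over records,
# summing species masses cell by cell without the vectorised gridding path.
brute_force_totals <- function(records, fleet, policy, grid,
                               growth_years = 0) {
  tot <- stats::setNames(numeric(6), c("SO2", "SO4_primary", "NOx",
                                       "PM_EC_OC_ash", "CO", "CO2"))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    cell <- shipimpact:::grid_cell_id(grid, r$lon, r$lat)
    if (is.na(cell)) next
    spec <- fleet[fleet$vessel_id == r$vessel_id, ]
    load <- propulsion_load(r$speed_mps, spec$design_speed_mps)
    sfoc <- sfoc_at_load(spec$base_sfoc, load)
    s <- applicable_sulphur(r$lon, r$lat, r$timestamp, policy)
    sox <- sox_split(s, sfoc, spec$fuel_family)
    e <- spec$installed_power_kw * load *
      project_growth(1, spec$ship_type, growth_years)
    so4m <- 3 * sox$ef_so4s
    tot["SO2"] <- tot["SO2"] + e * sox$ef_so2
    tot["SO4_primary"] <- tot["SO4_primary"] + e * so4m
    tot["NOx"] <- tot["NOx"] +
      e * nox_ef(spec$nox_tier, spec$engine_class, spec$crankshaft_rpm)
    tot["PM_EC_OC_ash"] <- tot["PM_EC_OC_ash"] +
      e * max(pm_ef(s, load) - so4m, 0)
    tot["CO"] <- tot["CO"] + e * shipimpact:::co_ef(load)
    tot["CO2"] <- tot["CO2"] + e * co2_ef(spec$fuel_family, sfoc)
  }
  tot / 1e6  # tonnes
}
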