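#' Propulsion engine load from speed
#'
#' Cubic propeller law: load scales with the cube of the speed ratio,
#' clamped to a hotelling floor (auxiliary demand while stationary) and a
#' cap of full power.
#'
#' @param speed Vessel speed, m/s (non-negative).
#' @param design_speed Design speed, m/s (positive).
#' @param floor Minimum load fraction (hotelling), default 0.02.
#' @param cap Maximum load fraction, default 1.
#' @return Load fraction in `[floor, cap]`.
#' @examples
#' propulsion_load(6.3, 10)  # ~0.25
#' @export
propulsion_load <- function(speed, design_speed, floor = 0.02, cap = 1) {
  if (any(speed < 0)) stop("`speed` must be non-negative", call. = FALSE)
  if (any(design_speed <= 0)) stop("`design_speed` must be positive", call. = FALSE)
  clamp((speed / design_speed)^3, floor, cap)
}

# Relative SFOC curve; the constants reproduce the registry-style low-load
# penalty (about +13% at quarter load relative to the 80%-load optimum).
sfoc_rel <- function(load) 0.455 * load^2 - 0.71 * load + 1.28

#' Load-dependent specific fuel-oil consumption
#'
#' Base SFOC is defined at 80% engine load; off-design loads pay a quadratic
#' penalty: `sfoc = base_sfoc * q(load) / q(0.8)` with
#' `q(L) = 0.455 L^2 - 0.71 L + 1.28`. At 25% load a 165 g/kWh engine burns
#' 186 g/kWh and a 250 g/kWh engine burns 282 g/kWh.
#'
#' @param base_sfoc Base SFOC at 80% load, g/kWh.
#' @param load Engine load fraction in (0, 1].
#' @return SFOC at `load`, g/kWh.
#' @export
sfoc_at_load <- function(base_sfoc, load) {
  if (any(base_sfoc <= 0)) stop("`base_sfoc` must be positive", call. = FALSE)
  if (any(load <= 0 | load > 1)) {
    stop("`load` must be in (0, 1]", call. = FALSE)
  }
  base_sfoc * sfoc_rel(load) / sfoc_rel(0.8)
}

#' NOx emission factor by MARPOL Annex VI tier
#'
#' Slow-speed (rpm < 130), medium-speed (130 <= rpm < 2000) and high-speed
#' (rpm >= 2000) diesels follow the Regulation 13 curves: Tier I
#' 17 / 45 n^-0.2 / 9.8, Tier II 14.4 / 44 n^-0.23 / 7.7, Tier III
#' 3.4 / 9 n^-0.2 / 2.0 g/kWh. Pre-regulation Tier 0 engines are assigned
#' 110% of the Tier I value.
#'
#' @param tier NOx tier, 0-3.
#' @param engine_class `"SSD"`, `"MSD"` or `"HSD"`.
#' @param rpm Crankshaft speed, rev/min (needed for MSD).
#' @return Emission factor, g/kWh.
#' @examples
#' nox_ef(2, "MSD", 514)  # 10.5
#' @export
nox_ef <- function(tier, engine_class, rpm = NULL) {
  n <- max(length(tier), length(engine_class), length(rpm))
  tier <- rep_len(tier, n)
  engine_class <- rep_len(engine_class, n)
  rpm <- if (is.null(rpm)) rep_len(NA_real_, n) else rep_len(rpm, n)
  if (any(!tier %in% 0:3)) stop("unknown NOx tier", call. = FALSE)
  if (any(!engine_class %in% c("SSD", "MSD", "HSD"))) {
    stop("unknown engine class", call. = FALSE)
  }
  if (any(engine_class == "MSD" & (is.na(rpm) | rpm <= 0))) {
    stop("`rpm` required (positive) for MSD engines", call. = FALSE)
  }
  tier1 <- ifelse(engine_class == "SSD", 17,
                  ifelse(engine_class == "MSD", 45 * rpm^(-0.2), 9.8))
  tier2 <- ifelse(engine_class == "SSD", 14.4,
                  ifelse(engine_class == "MSD", 44 * rpm^(-0.23), 7.7))
  tier3 <- ifelse(engine_class == "SSD", 3.4,
                  ifelse(engine_class == "MSD", 9 * rpm^(-0.2), 2.0))
  ifelse(tier == 0, 1.1 * tier1,
         ifelse(tier == 1, tier1, ifelse(tier == 2, tier2, tier3)))
}

# Sulphate-bound sulphur fraction closing the fuel-sulphur mass balance;
# inferred from the gaseous-SO2 / total-sulphur ratios by fuel family.
so4_s_fraction <- function(fuel_family) {
  if (any(!fuel_family %in% c("HFO", "MDO_MGO"))) {
    stop("unknown fuel family", call. = FALSE)
  }
  ifelse(fuel_family == "HFO", 0.063, 0.04)
}

#' Split fuel sulphur into gaseous SO2 and primary sulphate
#'
#' Fuel sulphur mass per kWh is `s_frac * sfoc`. A fuel-family-dependent
#' fraction `f` of that sulphur leaves the stack bound in primary sulphate
#' aerosol (0.04 for distillates, 0.063 for heavy fuel oil); the rest is
#' emitted as gaseous SO2 (factor 2 converts S mass to SO2 mass). Sulphur
#' mass balance `s_frac * sfoc = ef_so2 / 2 + ef_so4s` holds exactly.
#'
#' @param s_frac Fuel sulphur mass fraction (0 to 0.035).
#' @param sfoc Specific fuel-oil consumption, g/kWh.
#' @param fuel_family `"HFO"` or `"MDO_MGO"`.
#' @return List with `ef_so2` (g SO2 / kWh) and `ef_so4s`
#'   (g sulphate-bound S / kWh).
#' @examples
#' sox_split(0.005, 250, "MDO_MGO")$ef_so2  # 2.40
#' @export
sox_split <- function(s_frac, sfoc, fuel_family) {
  if (any(s_frac < 0)) stop("`s_frac` must be non-negative", call. = FALSE)
  if (any(s_frac > 0.035)) stop("`s_frac` above 3.5% is not a marine fuel",
                                call. = FALSE)
  f <- so4_s_fraction(fuel_family)
  list(ef_so2 = 2 * s_frac * sfoc * (1 - f),
       ef_so4s = s_frac * sfoc * f)
}

# PM anchors (g/kWh): rows = fuel sulphur fraction, cols = load 0.8 / 0.25
pm_anchor_s <- c(0.001, 0.005, 0.027)
pm_anchor_hi <- c(0.38, 0.50, 1.19)   # at 80% load
pm_anchor_lo <- c(0.43, 0.57, 1.35)   # at 25% load

#' Total particulate-matter emission factor
#'
#' Piecewise-linear in fuel sulphur between the anchors at 0.1%, 0.5% and
#' 2.7% S, linear in engine load between the 25% and 80% load points, with
#' constant (clamped) extrapolation outside both ranges. The PM total
#' includes the primary-sulphate mass.
#'
#' @param s_frac Fuel sulphur mass fraction.
#' @param load Engine load fraction in (0, 1].
#' @return Emission factor, g/kWh.
#' @export
pm_ef <- function(s_frac, load) {
  if (any(load <= 0 | load > 1)) stop("`load` must be in (0, 1]", call. = FALSE)
  s <- clamp(s_frac, pm_anchor_s[1], pm_anchor_s[3])
  hi <- stats::approx(pm_anchor_s, pm_anchor_hi, xout = s)$y
  lo <- stats::approx(pm_anchor_s, pm_anchor_lo, xout = s)$y
  w <- clamp((load - 0.25) / (0.8 - 0.25), 0, 1)
  lo + w * (hi - lo)
}

# CO emission factor, linear in load between the 25% and 80% points,
# clamped outside.
co_ef <- function(load) {
  w <- clamp((load - 0.25) / (0.8 - 0.25), 0, 1)
  2.18 + w * (0.54 - 2.18)
}

#' CO2 emission factor from fuel consumption
#'
#' Proportional to SFOC with a fuel-family carbon factor: 515/165 g CO2 per
#' g fuel for heavy fuel oil, 803/250 for distillates.
#'
#' @param fuel_family `"HFO"` or `"MDO_MGO"`.
#' @param sfoc SFOC, g/kWh.
#' @return Emission factor, g/kWh.
#' @export
co2_ef <- function(fuel_family, sfoc) {
  if (any(sfoc < 0)) stop("`sfoc` must be non-negative", call. = FALSE)
  if (any(!fuel_family %in% c("HFO", "MDO_MGO"))) {
    stop("unknown fuel family", call. = FALSE)
  }
  cf <- ifelse(fuel_family == "HFO", 515 / 165, 803 / 250)
  cf * sfoc
}

#' Construct a fuel-sulphur policy
#'
#' A policy is a global fuel-sulphur cap plus zero or more regional control
#' areas, each a polygon with its own (stricter) cap and an effective date.
#' Under business-as-usual the global residual-fuel sulphur content is 2.7%;
#' under the 2020 Action scenario the global cap is 0.5%. Control areas of
#' the kind in force regardless of the global decision: IMO emission control
#' areas at 0.1% S, EU-directive and Chinese domestic control areas at
#' 0.5% S.
#'
#' @param scenario `"BAU"`, `"ACTION_2020"`, or `"NO_SHIPPING"`.
#' @param regions List of regions, each
#'   `list(name =, polygon = matrix(lon, lat), s_cap =, effective_date =)`
#'   (`effective_date` a `Date`; defaults to already in force).
#' @return Object of class `fuel_policy`.
#' @export
fuel_policy <- function(scenario = c("BAU", "ACTION_2020", "NO_SHIPPING"),
                        regions = list()) {
  scenario <- match.arg(scenario)
  global <- switch(scenario, BAU = 0.027, ACTION_2020 = 0.005,
                   NO_SHIPPING = 0.027)
  for (r in regions) {
    if (is.null(r$polygon) || !is.matrix(r$polygon) || ncol(r$polygon) != 2 ||
        nrow(r$polygon) < 3) {
      stop("each region needs a polygon matrix with columns lon, lat",
           call. = FALSE)
    }
    if (is.null(r$s_cap) || r$s_cap < 0 || r$s_cap > 0.035) {
      stop("each region needs an s_cap in [0, 0.035]", call. = FALSE)
    }
  }
  structure(list(scenario = scenario, global_s_frac = global,
                 regions = regions),
            class = "fuel_policy")
}

#' Rectangular control-area helper
#'
#' @param lon_min,lon_max,lat_min,lat_max Box bounds, degrees.
#' @param s_cap Sulphur cap inside the box.
#' @param name Region label.
#' @param effective_date `Date` the cap enters into force.
#' @return A region list usable in [fuel_policy()].
#' @export
policy_box <- function(lon_min, lon_max, lat_min, lat_max, s_cap,
                       name = "box", effective_date = as.Date("2015-01-01")) {
  list(name = name,
       polygon = cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
                       lat = c(lat_min, lat_min, lat_max, lat_max)),
       s_cap = s_cap, effective_date = effective_date)
}

#' Effective fuel sulphur content at a position and date
#'
#' The strictest applicable cap: the minimum of the policy's global sulphur
#' content and the caps of every control area whose polygon contains the
#' position and whose effective date has passed.
#'
#' @param lon,lat Position, degrees.
#' @param date `Date` (or POSIXct) of the activity record.
#' @param policy A `fuel_policy`.
#' @return Effective fuel sulphur mass fraction (vectorised over positions).
#' @export
applicable_sulphur <- function(lon, lat, date, policy) {
  stopifnot(inherits(policy, "fuel_policy"))
  s <- rep_len(policy$global_s_frac, length(lon))
  date <- as.Date(date)
  pts <- cbind(lon, lat)
  for (r in policy$regions) {
    eff <- if (is.null(r$effective_date)) TRUE else date >= r$effective_date
    inside <- mgcv::in.out(rbind(r$polygon, r$polygon[1, ]), pts)
    s <- ifelse(inside & eff, pmin(s, r$s_cap), s)
  }
  s
}

# Table of compound annual growth rates by ship type (energy-based).
growth_rates_default <- c(dry_bulk = 0.0174, liquid_bulk = -0.0190,
                          unitised = 0.0279, passenger = -0.0055,
                          miscellaneous = 0.0000)

#' Project energy or emissions forward with compound growth
#'
#' @param value Base-year value(s).
#' @param ship_type One of `dry_bulk`, `liquid_bulk`, `unitised`,
#'   `passenger`, `miscellaneous` (vectorised).
#' @param n_years Projection horizon in years (>= 0).
#' @param rates Named vector of compound annual growth rates; defaults to
#'   the energy-based fleet rates (dry bulk +1.74%/yr, liquid bulk -1.90%,
#'   unitised +2.79%, passenger -0.55%, miscellaneous 0.00%).
#' @return `value * (1 + rate)^n_years`.
#' @export
project_growth <- function(value, ship_type, n_years,
                           rates = growth_rates_default) {
  if (n_years < 0) stop("`n_years` must be >= 0", call. = FALSE)
  if (any(!ship_type %in% names(rates))) {
    stop("unknown ship type: ",
         paste(setdiff(unique(ship_type), names(rates)), collapse = ", "),
         call. = FALSE)
  }
  value * unname((1 + rates[ship_type])^n_years)
}

emission_species <- c("SO2", "SO4_primary", "NOx", "PM_EC_OC_ash",
                      "CO", "CO2")

# Per-record emission factors and energies; shared by grid_emissions() and
# the brute-force oracle in the tests. Returns a data.frame with one row per
# record: energy_kwh and grams of each species.
record_emissions <- function(records, fleet, policy, growth_years = 0,
                             rates = growth_rates_default,
                             dt_hours = 1) {
  m <- match(records$vessel_id, fleet$vessel_id)
  if (anyNA(m)) stop("activity records reference vessels missing from the fleet",
                     call. = FALSE)
  spec <- fleet[m, ]
  load <- propulsion_load(records$speed_mps, spec$design_speed_mps)
  sfoc <- sfoc_at_load(spec$base_sfoc, load)
  s_frac <- applicable_sulphur(records$lon, records$lat, records$timestamp,
                               policy)
  sox <- sox_split(s_frac, sfoc, spec$fuel_family)
  ef_nox <- nox_ef(spec$nox_tier, spec$engine_class, spec$crankshaft_rpm)
  ef_pm_total <- pm_ef(s_frac, load)
  so4_mass <- 3 * sox$ef_so4s  # SO4/S molar mass ratio 96/32
  ef_rest <- pmax(ef_pm_total - so4_mass, 0)
  energy <- spec$installed_power_kw * load * dt_hours
  g <- if (growth_years > 0) {
    project_growth(1, spec$ship_type, growth_years, rates)
  } else 1
  data.frame(
    energy_kwh = energy * g,
    SO2 = energy * g * sox$ef_so2,
    SO4_primary = energy * g * so4_mass,
    NOx = energy * g * ef_nox,
    PM_EC_OC_ash = energy * g * ef_rest,
    CO = energy * g * co_ef(load),
    CO2 = energy * g * co2_ef(spec$fuel_family, sfoc))
}

#' Grid vessel activity into a scenario emission inventory
#'
#' For each activity record: engine load from the cubic propeller law,
#' load-corrected SFOC, position- and date-dependent fuel sulphur from the
#' policy, per-species emission factors, energy = installed power x load x
#' record interval, and accumulation of the resulting masses into the
#' containing grid cell. Species: gaseous SO2, primary sulphate (as SO4
#' mass), NOx, residual PM (elemental/organic carbon and ash, i.e. total PM
#' minus the sulphate mass), CO and CO2. Masses are accumulated in grams
#' internally and reported in tonnes. Records outside the grid are counted
#' and excluded.
#'
#' @param records A `vessel_activity` data.frame.
#' @param fleet A `vessel_fleet` covering every `vessel_id` in `records`.
#' @param policy A `fuel_policy`.
#' @param world A `synthetic_world` (or a bare `world_grid`).
#' @param growth_years Compound-growth projection horizon applied per ship
#'   type (0 = base year).
#' @param rates Growth-rate table for [project_growth()].
#' @param dt_hours Interval represented by one record, hours.
#' @return Object of class `emission_grid`: list with `grid`, `scenario`,
#'   `period_hours`, `species` (named list of `n_lat x n_lon` matrices,
#'   tonnes per period), `energy_kwh`, `n_records`, `n_excluded`.
#' @export
grid_emissions <- function(records, fleet, policy, world, growth_years = 0,
                           rates = growth_rates_default, dt_hours = 1) {
  grid <- if (inherits(world, "world_grid")) world else world$grid
  period_hours <- if (nrow(records) > 0) {
    as.numeric(difftime(max(records$timestamp), min(records$timestamp),
                        units = "hours")) + dt_hours
  } else 0
  species <- stats::setNames(
    lapply(emission_species, function(s) empty_field(grid)), emission_species)
  if (nrow(records) == 0) {
    return(structure(list(grid = grid, scenario = policy$scenario,
                          period_hours = period_hours, species = species,
                          energy_kwh = 0, n_records = 0L, n_excluded = 0L),
                     class = "emission_grid"))
  }
  cell <- grid_cell_id(grid, records$lon, records$lat)
  keep <- !is.na(cell)
  n_excluded <- sum(!keep)
  em <- record_emissions(records[keep, , drop = FALSE], fleet, policy,
                         growth_years, rates, dt_hours)
  cell <- cell[keep]
  for (s in emission_species) {
    acc <- rowsum(em[[s]], cell)                 # grams
    species[[s]][as.integer(rownames(acc))] <- acc[, 1] / 1e6  # tonnes
  }
  structure(list(grid = grid, scenario = policy$scenario,
                 period_hours = period_hours, species = species,
                 energy_kwh = sum(em$energy_kwh),
                 n_records = sum(keep), n_excluded = n_excluded),
            class = "emission_grid")
}

#' @export
print.emission_grid <- function(x, ...) {
  tot <- vapply(x$species, sum, 0)
  cat(sprintf("<emission_grid> scenario %s, %d records (%d excluded), %.0f h period\n",
              x$scenario, x$n_records, x$n_excluded, x$period_hours))
  for (s in names(tot)) cat(sprintf("  %-13s %12.4f t\n", s, tot[s]))
  invisible(x)
}

#' Per-species emission totals of an inventory
#'
#' @param emis An `emission_grid`.
#' @return Named numeric vector of totals in tonnes per period.
#' @export
emission_totals <- function(emis) {
  vapply(emis$species, sum, 0)
}
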