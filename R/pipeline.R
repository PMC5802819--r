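#' Validate a scenario configuration
#'
#' A configuration drives the whole pipeline: one synthetic world shared by
#' all scenarios, the traffic fleet, the fuel-sulphur policies, the
#' concentration-response choice and the forcing options. Accepts a list or
#' a YAML file path. Required fields: `seed`, `world`, `traffic`, `policy`;
#' optional: `scenarios` (default all three), `growth_years` (default 5),
#' `cr_form` (default `"linear"`), `forcing` (ssa, mixing_mode,
#' detachment), `exposure` overrides.
#'
#' @param config List or path to a YAML file.
#' @return Validated config list of class `scenario_config`.
#' @export
scenario_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  required <- c("seed", "world", "traffic", "policy")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("scenario config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  defaults <- list(
    scenarios = c("NO_SHIPPING", "BAU", "ACTION_2020"),
    growth_years = 5, cr_form = "linear",
    forcing = list(ssa = 0.999, mixing_mode = "well_mixed",
                   detachment = 0.25),
    exposure = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  wd <- config$world
  wdef <- list(lon_min = -10, lon_max = 10, lat_min = 30, lat_max = 50,
               cell_size = 1, n_countries = 3, coastal_bias = 3,
               total_population = 1e7, land_fraction = 0.35)
  for (nm in names(wdef)) if (is.null(wd[[nm]])) wd[[nm]] <- wdef[[nm]]
  config$world <- wd
  td <- config$traffic
  tdef <- list(n_lanes = 3, n_vessels = 50, period_hours = 168)
  for (nm in names(tdef)) if (is.null(td[[nm]])) td[[nm]] <- tdef[[nm]]
  config$traffic <- td
  if (!all(config$scenarios %in% c("NO_SHIPPING", "BAU", "ACTION_2020"))) {
    stop("unknown scenario id in config", call. = FALSE)
  }
  structure(config, class = c("scenario_config", "list"))
}

#' Run the full scenario pipeline
#'
#' Stages, in order: synthetic world, fleet and traffic; per-scenario fuel
#' policy, emission inventory (with compound growth to the horizon year),
#' steady-state concentrations and total PM2.5; health burden of each
#' scenario against the no-shipping counterfactual; direct and
#' first-indirect forcing of each scenario's ship aerosol. The
#' ammonium-nitrate compensation of the Action scenario's sulphate
#' reduction (relative to BAU) is applied when both scenarios run. All
#' randomness is confined to the world-generation stage; downstream stages
#' are pure transforms, so reruns with the same config are bit-identical.
#'
#' @param config A `scenario_config` (or list / YAML path accepted by it).
#' @param out_dir Optional directory; when given, gridded fields and tables
#'   are written as CSV plus a JSON run manifest.
#' @return List of class `pipeline_result` with `world`, `fleet`,
#'   `traffic`, `meteo`, `background`, per-scenario `runs` (emissions,
#'   concentration, burdens, forcing), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- scenario_config(config)
  t_start <- Sys.time()
  grid <- world_grid(config$world$lon_min, config$world$lon_max,
                     config$world$lat_min, config$world$lat_max,
                     config$world$cell_size)
  world <- generate_world(config$seed, grid,
                          n_countries = config$world$n_countries,
                          coastal_bias = config$world$coastal_bias,
                          total_population = config$world$total_population,
                          land_fraction = config$world$land_fraction)
  fleet <- generate_fleet(config$seed, config$traffic$n_vessels)
  traffic <- generate_traffic(config$seed, world,
                              n_lanes = config$traffic$n_lanes,
                              n_vessels = config$traffic$n_vessels,
                              period_hours = config$traffic$period_hours,
                              design_speed_mps = fleet$design_speed_mps)
  meteo <- generate_meteo(config$seed, world)
  background <- generate_background(config$seed, world, meteo)
  incidence <- generate_incidence(config$seed, world$cohorts$country)
  lifetimes <- do.call(species_lifetimes,
                       config$exposure[names(config$exposure) %in%
                                         c("tau_so2", "tau_so4", "tau_no3",
                                           "tau_primary")])
  regions <- config$policy$regions %||% list()

  runs <- list()
  for (sc in config$scenarios) {
    policy <- fuel_policy(sc, regions)
    recs <- if (sc == "NO_SHIPPING") traffic[0, , drop = FALSE] else traffic
    emis <- grid_emissions(recs, fleet, policy, world,
                           growth_years = config$growth_years)
    conc_ship <- steady_state_concentration(emis, meteo, lifetimes)
    conc <- assemble_pm25(conc_ship, background)
    runs[[sc]] <- list(scenario = sc, policy = policy, emissions = emis,
                       concentration = conc)
  }

  # ammonium-nitrate compensation of the Action sulphate reduction vs BAU
  if (all(c("BAU", "ACTION_2020") %in% names(runs))) {
    dso4 <- runs$ACTION_2020$concentration$components$so4 -
      runs$BAU$concentration$components$so4
    offset <- nitrate_compensation(dso4)
    act <- runs$ACTION_2020$concentration
    act$components$no3 <- act$components$no3 + offset
    act$total <- act$total + offset
    runs$ACTION_2020$concentration <- act
    runs$ACTION_2020$nitrate_offset <- offset
  }

  if ("NO_SHIPPING" %in% names(runs)) {
    c0 <- runs$NO_SHIPPING$concentration$total
    for (sc in setdiff(names(runs), "NO_SHIPPING")) {
      c1 <- runs[[sc]]$concentration$total
      runs[[sc]]$burdens <- lapply(c(CV = "CV", LC = "LC", ASTHMA = "ASTHMA"),
                                   function(ep) {
        health_burden(cr_model(ep, form = config$cr_form), c0, c1, world,
                      incidence)
      })
      runs[[sc]]$forcing <- scenario_forcing(runs[[sc]], runs$NO_SHIPPING,
                                             meteo, grid, config$forcing)
    }
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("shipimpact")),
    started = format(t_start, tz = "UTC"),
    finished = format(Sys.time(), tz = "UTC"),
    stage_checksums = list(
      world = rlang::hash(world),
      traffic = rlang::hash(traffic),
      emissions = lapply(runs, function(r) rlang::hash(r$emissions$species)),
      concentration = lapply(runs, function(r) rlang::hash(r$concentration$total))))

  result <- structure(list(config = config, world = world, fleet = fleet,
                           traffic = traffic, meteo = meteo,
                           background = background, incidence = incidence,
                           runs = runs, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct + first-indirect forcing of one scenario's ship aerosol against
# the no-shipping counterfactual.
scenario_forcing <- function(run, base_run, meteo, grid, opts) {
  optics <- aerosol_optics(ssa = opts$ssa %||% 0.999)
  dso4 <- run$concentration$components$so4 -
    base_run$concentration$components$so4
  dno3 <- run$concentration$components$no3 -
    base_run$concentration$components$no3
  daod <- aod_of_concentration(pmax(dso4 + dno3, 0), meteo, optics)
  direct <- direct_forcing(daod, optics, meteo, grid)
  ind <- indirect_forcing(meteo, grid,
                          c_nss_base = base_run$concentration$components$so4,
                          c_nss_pert = run$concentration$components$so4,
                          mixing_mode = opts$mixing_mode %||% "well_mixed",
                          detachment = opts$detachment %||% 0.25)
  list(direct = direct$global_mw_m2, indirect = ind$global_mw_m2,
       direct_field = direct$cell_mw_m2, indirect_field = ind$cell_mw_m2)
}

#' Compare two scenario runs
#'
#' Emission totals per pollutant with deltas and percent reductions, health
#' burden with confidence bounds plus the avoided burden between the
#' scenarios, and the forcing component table.
#'
#' @param result A `pipeline_result`.
#' @param base,alt Scenario ids present in `result$runs` (defaults BAU vs
#'   ACTION_2020).
#' @param rounded Apply report rounding (mortality nearest 100, asthma
#'   nearest 100,000, forcing to integer mW/m^2) to the tables.
#' @return List with data.frames `emissions`, `health`, `forcing`.
#' @export
compare_scenarios <- function(result, base = "BAU", alt = "ACTION_2020",
                              rounded = FALSE) {
  stopifnot(inherits(result, "pipeline_result"))
  for (sc in c(base, alt)) {
    if (is.null(result$runs[[sc]])) {
      stop("scenario not present in this run: ", sc, call. = FALSE)
    }
  }
  rb <- result$runs[[base]]; ra <- result$runs[[alt]]
  if (!same_grid(rb$emissions$grid, ra$emissions$grid)) {
    stop("scenario runs are on different worlds; comparison refused",
         call. = FALSE)
  }
  tb <- emission_totals(rb$emissions); ta <- emission_totals(ra$emissions)
  emissions <- data.frame(species = names(tb), base = unname(tb),
                          alt = unname(ta), delta = unname(ta - tb),
                          percent_reduction = ifelse(tb > 0,
                                                     100 * (tb - ta) / tb,
                                                     NA_real_))

  health <- NULL
  if (!is.null(rb$burdens)) {
    rows <- lapply(names(rb$burdens), function(ep) {
      b0 <- rb$burdens[[ep]]; b1 <- ra$burdens[[ep]]
      data.frame(endpoint = ep,
                 base_central = b0$total, base_low = b0$total_low,
                 base_high = b0$total_high,
                 alt_central = b1$total, alt_low = b1$total_low,
                 alt_high = b1$total_high,
                 avoided = b0$total - b1$total,
                 percent_reduction = percent_reduction(b0$total, b1$total))
    })
    health <- do.call(rbind, rows)
    comb <- health[health$endpoint %in% c("CV", "LC"), ]
    if (nrow(comb) == 2) {
      sums <- colSums(comb[, 2:8])
      health <- rbind(health, data.frame(
        endpoint = "COMBINED", base_central = sums[["base_central"]],
        base_low = sums[["base_low"]], base_high = sums[["base_high"]],
        alt_central = sums[["alt_central"]], alt_low = sums[["alt_low"]],
        alt_high = sums[["alt_high"]], avoided = sums[["avoided"]],
        percent_reduction = percent_reduction(sums[["base_central"]],
                                              sums[["alt_central"]])))
    }
    if (rounded) {
      for (col in c("base_central", "base_low", "base_high", "alt_central",
                    "alt_low", "alt_high", "avoided")) {
        health[[col]] <- mapply(report_round, health[[col]], health$endpoint)
      }
    }
  }

  forcing <- NULL
  if (!is.null(rb$forcing)) {
    forcing <- forcing_report(rb$forcing[c("direct", "indirect")],
                              ra$forcing[c("direct", "indirect")])
    if (rounded) {
      for (col in c("bau", "action", "net_change")) {
        forcing[[col]] <- round(forcing[[col]])
      }
    }
  }

  list(emissions = emissions, health = health, forcing = forcing)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> scenarios: %s on a %dx%d world (seed %s)\n",
              paste(names(x$runs), collapse = ", "),
              x$world$grid$n_lat, x$world$grid$n_lon, x$config$seed))
  invisible(x)
}
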