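# Build a bare emission inventory with prescribed per-cell masses (tonnes).
make_emis <- function(grid, species = list(), period_hours = 24,
                      scenario = "BAU") {
  base <- stats::setNames(
    lapply(shipimpact:::emission_species, function(s) {
      matrix(0, grid$n_lat, grid$n_lon)
    }), shipimpact:::emission_species)
  for (nm in names(species)) base[[nm]] <- species[[nm]]
  structure(list(grid = grid, scenario = scenario,
                 period_hours = period_hours, species = base,
                 energy_kwh = 0, n_records = 0L, n_excluded = 0L),
            class = "emission_grid")
}

flat_meteo <- function(grid, wind = 0, hmix = 1000) {
  f <- function(v) matrix(v, grid$n_lat, grid$n_lon)
  structure(list(cloud_fraction = f(0.5), insolation = f(250),
                 wind_speed = f(wind), mixing_height = f(hmix),
                 sea_salt = f(5), albedo = f(0.06)),
            class = "meteo_fields")
}

test_that("a single no-wind emitter matches the closed-form box solution", {
  g <- tiny_grid()
  # engineer the column so that area x mixing height = 1e11 m^3,
  # the hand-checked configuration: 1 g/s for 2.8 d -> 2.4192 ug/m3
  cell <- c(10, 10)
  period_h <- 24
  mass_t <- 1 * period_h * 3600 / 1e6  # 1 g/s over the period
  so2 <- matrix(0, g$n_lat, g$n_lon)
  emis_so4 <- matrix(0, g$n_lat, g$n_lon)
  emis_so4[cell[1], cell[2]] <- mass_t
  emis <- make_emis(g, list(SO4_primary = emis_so4), period_hours = period_h)
  met <- flat_meteo(g, wind = 0)
  met$mixing_height[] <- 1e11 / g$cell_area_m2
  conc <- steady_state_concentration(emis, met, species_lifetimes())
  expect_equal(conc$components$so4[cell[1], cell[2]],
               1e6 * 2.8 * 86400 / 1e11, tolerance = 1e-9)  # 2.4192
  # with no wind nothing leaves the source cell
  expect_equal(sum(conc$components$so4 > 0), 1)
  # other components untouched
  expect_true(all(conc$components$primary == 0))
})

test_that("zero emissions give zero ship-attributable concentration", {
  g <- tiny_grid()
  conc <- steady_state_concentration(make_emis(g), flat_meteo(g, wind = 5))
  expect_true(all(conc$total == 0))
})

test_that("concentrations are linear in emissions and in the lifetime", {
  g <- tiny_grid()
  set.seed(9)
  m <- matrix(rexp(g$n_lat * g$n_lon, 10), g$n_lat, g$n_lon)
  met <- flat_meteo(g, wind = 4)
  c1 <- steady_state_concentration(make_emis(g, list(SO4_primary = m)), met)
  c2 <- steady_state_concentration(make_emis(g, list(SO4_primary = 2 * m)), met)
  expect_equal(c2$components$so4, 2 * c1$components$so4, tolerance = 1e-12)
  # no negative concentrations anywhere
  expect_true(all(c1$total >= 0))
  # with no wind, doubling the sulphate lifetime doubles the field
  met0 <- flat_meteo(g, wind = 0)
  a <- steady_state_concentration(make_emis(g, list(SO4_primary = m)), met0,
                                  species_lifetimes(tau_so4 = 2.8))
  b <- steady_state_concentration(make_emis(g, list(SO4_primary = m)), met0,
                                  species_lifetimes(tau_so4 = 5.6))
  expect_equal(b$components$so4, 2 * a$components$so4, tolerance = 1e-12)
})

test_that("the spreading kernel conserves column mass on the closed domain", {
  g <- tiny_grid()
  set.seed(14)
  mass <- matrix(0, g$n_lat, g$n_lon)
  mass[sample(length(mass), 15)] <- runif(15, 1, 100)
  ell <- matrix(runif(length(mass), 1e4, 5e5), g$n_lat, g$n_lon)
  out <- shipimpact:::spread_mass(g, mass, ell)
  expect_equal(sum(out), sum(mass), tolerance = 1e-9)
  expect_true(all(out >= 0))
  # zero e-folding length leaves the mass in place
  out0 <- shipimpact:::spread_mass(g, mass, ell * 0)
  expect_equal(out0, mass)
})

test_that("SO2 oxidation routes the configured sulphur share to sulphate", {
  g <- tiny_grid()
  so2 <- matrix(0, g$n_lat, g$n_lon); so2[5, 5] <- 64  # tonnes SO2 = 32 t S
  met <- flat_meteo(g, wind = 0)
  conc <- steady_state_concentration(make_emis(g, list(SO2 = so2)), met,
                                     so2_to_so4 = 0.5)
  # 50% of 32 t S -> 16 t S -> 48 t SO4; column conc = Q tau / (A h)
  q <- 48 * 1e12 / (24 * 3600)
  expected <- q * 2.8 * 86400 / (g$cell_area_m2[5, 5] * 1000)
  expect_equal(conc$components$so4[5, 5], expected, tolerance = 1e-9)
  none <- steady_state_concentration(make_emis(g, list(SO2 = so2)), met,
                                     so2_to_so4 = 0)
  expect_true(all(none$components$so4 == 0))
})

test_that("nitrate compensation obeys the 1% mean and 15% local bounds", {
  dso4 <- matrix(-runif(400, 0, 3), 20, 20)
  off <- nitrate_compensation(dso4)
  expect_true(all(off >= 0))
  expect_equal(off, 0.01 * abs(dso4), tolerance = 1e-12)
  # mean offset share of the sulphate reduction stays at the default kappa
  expect_lte(mean(off) / mean(abs(dso4)), 0.01 + 1e-12)
  # high-ammonia cells may offset up to 15%, never more
  mask <- matrix(FALSE, 20, 20); mask[1:3, 1:3] <- TRUE
  off2 <- nitrate_compensation(dso4, high_ammonia = mask)
  expect_true(all(off2 <= 0.15 * abs(dso4) + 1e-12))
  expect_equal(off2[1, 1], 0.15 * abs(dso4[1, 1]))
  # capped by the available ammonia equivalent
  off3 <- nitrate_compensation(dso4, high_ammonia = mask,
                               ammonia_equiv = 0.001)
  expect_true(all(off3 <= 0.001 + 1e-15))
  # no sulphate change, no offset
  expect_true(all(nitrate_compensation(dso4 * 0) == 0))
  expect_error(nitrate_compensation(dso4, ammonia_equiv = -1), "non-negative")
})

test_that("PM2.5 assembly is an exact component sum over the background", {
  w <- open_sea_world()
  met <- generate_meteo(3, w)
  bg <- generate_background(3, w, met)
  fleet <- generate_fleet(3, 8)
  tr <- generate_traffic(3, w, n_lanes = 2, n_vessels = 8, period_hours = 24,
                         design_speed_mps = fleet$design_speed_mps)
  emis <- grid_emissions(tr, fleet, fuel_policy("BAU"), w)
  ship <- steady_state_concentration(emis, met)
  pm <- assemble_pm25(ship, bg)
  expect_equal(pm$total, Reduce(`+`, pm$components), tolerance = 1e-12)
  # all-zero ship components: total equals the background
  empty <- steady_state_concentration(make_emis(w$grid), met)
  pm0 <- assemble_pm25(empty, bg)
  expect_equal(pm0$total, bg$total, tolerance = 1e-12)
  # removing the ship source cannot raise concentrations anywhere
  expect_true(all(concentration_delta(pm, pm0) >= -1e-12))
})

test_that("sulphur burden diagnostic recovers flux-weighted lifetimes", {
  g <- tiny_grid()
  # equal sulphur sink fluxes: 64 t SO2 (32 t S) and 96 t SO4 (32 t S) per day
  so2 <- matrix(0, g$n_lat, g$n_lon); so2[1, 1] <- 64
  so4 <- matrix(0, g$n_lat, g$n_lon); so4[1, 1] <- 96
  d <- burden_diagnostic(make_emis(g, list(SO2 = so2, SO4_primary = so4)))
  expect_equal(d$mean_lifetime_days, (1.5 + 2.8) / 2)  # 2.15
  expect_equal(d$burden_tonnes_s, 32 * 1.5 + 32 * 2.8)
  # single species: mean lifetime equals that species' lifetime exactly
  d2 <- burden_diagnostic(make_emis(g, list(SO2 = so2)))
  expect_equal(d2$mean_lifetime_days, 1.5)
  # zero emissions: zero burden
  d0 <- burden_diagnostic(make_emis(g))
  expect_equal(d0$burden_tonnes_s, 0)
})

test_that("degenerate exposure configurations are rejected", {
  g <- tiny_grid()
  met <- flat_meteo(g)
  met$mixing_height[1, 1] <- 0
  expect_error(steady_state_concentration(make_emis(g), met), "mixing height")
  expect_error(species_lifetimes(tau_so2 = -1), "positive")
})
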