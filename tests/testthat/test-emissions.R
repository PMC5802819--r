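test_that("propulsion load follows the clamped cubic law", {
  expect_equal(propulsion_load(10, 10), 1)
  expect_equal(propulsion_load(0, 10), 0.02)     # hotelling floor
  expect_equal(propulsion_load(6.3, 10), 0.63^3) # 0.250 to 4 s.f.
  expect_equal(propulsion_load(6.3, 10), 0.250, tolerance = 5e-4)
  expect_equal(propulsion_load(15, 10), 1)       # capped at full power
  expect_error(propulsion_load(-1, 10), "non-negative")
  expect_error(propulsion_load(1, 0), "positive")
})

test_that("SFOC load curve reproduces the low-load registry values", {
  expect_equal(sfoc_at_load(165, 0.8), 165)      # normalisation point
  expect_equal(round(sfoc_at_load(165, 0.25)), 186)
  expect_equal(round(sfoc_at_load(250, 0.25)), 282)
  expect_error(sfoc_at_load(165, 0), "load")
  expect_error(sfoc_at_load(165, 1.2), "load")
})

test_that("NOx factors follow the MARPOL tier curves", {
  expect_equal(round(nox_ef(1, "MSD", 514), 1), 12.9)
  expect_equal(round(nox_ef(2, "MSD", 514), 1), 10.5)
  expect_equal(round(nox_ef(3, "MSD", 514), 1), 2.6)
  expect_equal(nox_ef(1, "SSD"), 17)
  expect_equal(nox_ef(2, "SSD"), 14.4)
  expect_equal(nox_ef(1, "HSD"), 9.8)
  expect_equal(nox_ef(3, "HSD"), 2.0)
  expect_equal(nox_ef(0, "SSD"), 1.1 * 17)       # Tier 0 = 110% of Tier I
  expect_error(nox_ef(5, "SSD"), "tier")
  expect_error(nox_ef(1, "MSD"), "rpm")
})

test_that("sulphur split matches the printed SO2 factors and mass balance", {
  expect_equal(round(sox_split(0.005, 250, "MDO_MGO")$ef_so2, 2), 2.40)
  expect_equal(round(sox_split(0.001, 250, "MDO_MGO")$ef_so2, 2), 0.48)
  expect_equal(round(sox_split(0.027, 165, "HFO")$ef_so2, 2), 8.35)
  # sulphur mass balance is exact for arbitrary inputs
  set.seed(42)
  for (i in 1:50) {
    s <- runif(1, 0, 0.035); fc <- runif(1, 150, 300)
    fuel <- sample(c("HFO", "MDO_MGO"), 1)
    sp <- sox_split(s, fc, fuel)
    expect_equal(sp$ef_so2 / 2 + sp$ef_so4s, s * fc, tolerance = 1e-12)
  }
  expect_error(sox_split(-0.01, 250, "MDO_MGO"), "non-negative")
  expect_error(sox_split(0.05, 250, "MDO_MGO"), "3.5%")
})

test_that("PM factor interpolates the sulphur anchors and load points", {
  expect_equal(pm_ef(0.005, 0.8), 0.50)
  expect_equal(pm_ef(0.027, 0.25), 1.35)
  expect_equal(pm_ef(0.001, 0.8), 0.38)
  expect_equal(pm_ef(0.016, 0.8), 0.845)  # midpoint of 0.50 and 1.19
  # clamped extrapolation outside the anchor span
  expect_equal(pm_ef(0.0005, 0.8), pm_ef(0.001, 0.8))
  expect_equal(pm_ef(0.03, 0.25), pm_ef(0.027, 0.25))
  expect_equal(pm_ef(0.005, 0.1), pm_ef(0.005, 0.25))
  # load interpolation midpoint
  expect_equal(pm_ef(0.005, 0.525), (0.50 + 0.57) / 2)
})

test_that("CO2 factor is proportional to SFOC with fuel carbon factors", {
  expect_equal(co2_ef("HFO", 165), 515)
  expect_equal(co2_ef("MDO_MGO", 250), 803)
  expect_equal(round(co2_ef("MDO_MGO", 282)), 906)  # table prints 905
  expect_equal(co2_ef("HFO", 0), 0)
  expect_error(co2_ef("LNG", 200), "fuel")
})

test_that("applicable sulphur takes the strictest in-force cap", {
  seca <- policy_box(0, 5, 45, 50, 0.001, "SECA")
  future <- policy_box(10, 15, 30, 35, 0.001, "late",
                       effective_date = as.Date("2021-01-01"))
  bau <- fuel_policy("BAU", list(seca, future))
  act <- fuel_policy("ACTION_2020", list(seca))
  d <- as.Date("2020-06-01")
  expect_equal(applicable_sulphur(10, 40, d, bau), 0.027)  # open ocean
  expect_equal(applicable_sulphur(2, 47, d, bau), 0.001)   # inside SECA
  expect_equal(applicable_sulphur(2, 47, d, act), 0.001)   # SECA < global
  expect_equal(applicable_sulphur(12, 32, d, bau), 0.027)  # not yet in force
  expect_equal(applicable_sulphur(12, 32, as.Date("2021-06-01"), bau), 0.001)
  expect_equal(applicable_sulphur(10, 40, d, act), 0.005)
  expect_error(fuel_policy("BAU", list(list(s_cap = 0.001))), "polygon")
})

test_that("compound growth projection matches the per-type rates", {
  expect_equal(round(project_growth(1, "dry_bulk", 5), 4), 1.0901)
  expect_equal(project_growth(1, "miscellaneous", 7), 1)
  expect_equal(project_growth(1, "liquid_bulk", 0), 1)
  expect_equal(project_growth(100, "unitised", 5), 100 * 1.0279^5,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(project_growth(1, "hovercraft", 5), "ship type")
  expect_error(project_growth(1, "dry_bulk", -1), ">= 0")
})

test_that("gridding matches hand arithmetic for a single record", {
  g <- tiny_grid()
  w <- open_sea_world()
  fleet <- one_vessel_fleet(power = 10000, design_speed = 10,
                            base_sfoc = 200, fuel = "MDO_MGO")
  sea <- which(!w$land, arr.ind = TRUE)[1, ]
  rec <- records_at(w$grid$lon[sea["col"]], w$grid$lat[sea["row"]],
                    speed = 0.8^(1 / 3) * 10, n = 1)
  pol <- fuel_policy("ACTION_2020")  # 0.5% S everywhere
  em <- grid_emissions(rec, fleet, pol, w)
  # 10,000 kW x 0.8 load x 1 h x ef_so2; ef at sfoc(200, 0.8) = 200
  ef <- sox_split(0.005, 200, "MDO_MGO")$ef_so2
  expect_equal(sum(em$species$SO2) * 1e6, 10000 * 0.8 * ef,
               tolerance = 1e-9)
  # spec example: ef_so2 = 2.40 -> 19.2 kg in the cell
  expect_equal(10000 * 0.8 * 2.40 / 1000, 19.2)
  expect_equal(em$n_records, 1L)
})

test_that("gridded totals equal a brute-force per-record loop", {
  w <- open_sea_world()
  fleet <- generate_fleet(31, 12)
  traffic <- generate_traffic(31, w, n_lanes = 2, n_vessels = 12,
                              period_hours = 24,
                              design_speed_mps = fleet$design_speed_mps)
  seca <- policy_box(0, 8, 30, 40, 0.001, "SECA")
  pol <- fuel_policy("BAU", list(seca))
  em <- grid_emissions(traffic, fleet, pol, w, growth_years = 5)
  oracle <- brute_force_totals(traffic, fleet, pol, w$grid, growth_years = 5)
  expect_equal(emission_totals(em), oracle, tolerance = 1e-10)
})

test_that("empty record lists give an all-zero inventory", {
  w <- open_sea_world()
  fleet <- generate_fleet(1, 3)
  em <- grid_emissions(records_at(1, 31, 5, n = 0), fleet,
                       fuel_policy("BAU"), w)
  expect_true(all(vapply(em$species, sum, 0) == 0))
})

test_that("records outside the grid are excluded and counted", {
  w <- open_sea_world()
  fleet <- one_vessel_fleet()
  sea <- which(!w$land, arr.ind = TRUE)[1, ]
  rec <- rbind(records_at(w$grid$lon[sea["col"]], w$grid$lat[sea["row"]], 5, 1),
               records_at(100, 0, 5, 1))  # outside the domain
  class(rec) <- c("vessel_activity", "data.frame")
  em <- grid_emissions(rec, fleet, fuel_policy("BAU"), w)
  expect_identical(em$n_excluded, 1L)
  expect_identical(em$n_records, 1L)
})

test_that("the low-sulphur policy reduces SO2 cell-wise and by 81.5% at sea", {
  w <- open_sea_world()
  fleet <- generate_fleet(13, 20)
  fleet$fuel_family <- "HFO"
  traffic <- generate_traffic(13, w, n_lanes = 3, n_vessels = 20,
                              period_hours = 48,
                              design_speed_mps = fleet$design_speed_mps)
  em_bau <- grid_emissions(traffic, fleet, fuel_policy("BAU"), w)
  em_act <- grid_emissions(traffic, fleet, fuel_policy("ACTION_2020"), w)
  # cell-wise monotonicity
  expect_true(all(em_act$species$SO2 <= em_bau$species$SO2 + 1e-12))
  # open-ocean fleet: closed-form (2.7 - 0.5)/2.7 reduction
  red <- 100 * (1 - sum(em_act$species$SO2) / sum(em_bau$species$SO2))
  expect_equal(red, 100 * (2.7 - 0.5) / 2.7, tolerance = 1e-6)
  # with a SECA capturing part of the traffic the reduction drops below it
  lane_cells <- unique(shipimpact:::grid_cell_id(w$grid, traffic$lon,
                                                 traffic$lat))
  r <- (lane_cells[1] - 1) %% w$grid$n_lat + 1
  c <- (lane_cells[1] - 1) %/% w$grid$n_lat + 1
  seca <- policy_box(w$grid$lon[c] - 3, w$grid$lon[c] + 3,
                     w$grid$lat[r] - 3, w$grid$lat[r] + 3, 0.001, "SECA")
  em_bau2 <- grid_emissions(traffic, fleet, fuel_policy("BAU", list(seca)), w)
  em_act2 <- grid_emissions(traffic, fleet,
                            fuel_policy("ACTION_2020", list(seca)), w)
  red2 <- 100 * (1 - sum(em_act2$species$SO2) / sum(em_bau2$species$SO2))
  expect_lt(red2, 100 * (2.7 - 0.5) / 2.7 - 1e-6)
})
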