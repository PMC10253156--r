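test_that("regulatory NOx limits step down by registration era", {
  lim <- euro_nox_limits()
  expect_equal(nox_limit(lim, "diesel", 2016), 80)
  expect_equal(nox_limit(lim, "diesel", 2012), 180)
  expect_equal(nox_limit(lim, "diesel", 1998), 900)
  expect_equal(nox_limit(lim, "petrol", 2012), 60)
  expect_equal(nox_limit(lim, "petrol", 2003), 150)
  expect_error(nox_limit(lim, "lpg", 2010), "lpg")
  expect_error(euro_nox_limits(data.frame(fuel = "diesel", from_year = 0,
                                          limit_mg_km = -5)), "positive")
})

test_that("legacy fleet emissions follow limit x distance x survivors", {
  flat <- flat_schedule(30)
  legacy <- data.frame(reg_year = 2015, fuel = "diesel", count = 1000)
  # 1000 diesels at the 80 mg/km tier over 15,125 km, all surviving
  expect_equal(legacy_fleet_nox(2016, legacy, schedule = flat),
               80 * 1000 * 15125 / 1e9)
  # cohorts aged past the maximum contribute nothing
  s <- calibrate_survival()
  old <- data.frame(reg_year = 1990, fuel = "diesel", count = 1e6)
  expect_equal(legacy_fleet_nox(2020, old, schedule = s), 0)
})

test_that("legacy contribution declines monotonically year-on-year", {
  s <- calibrate_survival()
  legacy <- legacy_fleet()
  series <- vapply(2020:2044, legacy_fleet_nox, numeric(1),
                   legacy = legacy, schedule = s)
  expect_true(all(diff(series) < 0))
  expect_equal(series[length(series)], 0)  # all legacy cohorts retired by 2044
})

test_that("whole-fleet NOx matches a brute-force enumeration on a toy fleet", {
  rates <- structure(
    data.frame(segment_key = c("B", "B"), fuel = c("petrol", "diesel"),
               count = c(60, 40), co2_t_per_vehicle = c(1, 2),
               nox_kg_per_vehicle = c(0.5, 2)),
    class = c("emission_rates", "data.frame"),
    phev_co2 = 0, phev_nox = 0, bev_share = 0)
  profiles <- suppressWarnings(build_segment_profiles(toy_fleet()))
  flat <- flat_schedule(3)
  legacy <- data.frame(reg_year = c(2019, 2018), fuel = c("diesel", "petrol"),
                       count = c(50, 80))
  sales <- function(year) 100
  got <- fleet_annual_nox(scenario_spec("BAU"), 2021, rates, profiles,
                          flat, legacy, sales = sales)
  # legacy: 50 diesels at 80 mg (age 2), 80 petrols at 60 mg (age 3 -> gone)
  legacy_t <- 80 * 50 * 15125 / 1e9
  # cohorts 2020 and 2021, both fully surviving, same composition:
  # 60 petrol x 0.5 kg + 40 diesel x 2 kg = 110 kg each
  expect_equal(got, legacy_t + 2 * 110 / 1000)
})

test_that("business-as-usual new-cohort NOx is constant across cohorts", {
  fl <- generate_fleet(fleet_gen_config(seed = 13))
  rates <- emission_rates(fl)
  profiles <- build_segment_profiles(fl)
  s <- calibrate_survival()
  sales <- sales_trajectory(2020, sum(fl$registrations))
  base_comp <- rates[, c("segment_key", "fuel", "count")]
  first_year <- vapply(2021:2026, function(cy) {
    cells <- compose_cohort(scenario_presets()$BAU, cy, base_comp, sales)
    sum(cells$count * fleetair:::.cell_nox_rate(cells, rates, profiles)) / 1000
  }, numeric(1))
  expect_equal(diff(first_year), rep(0, 5), tolerance = 1e-9)
})

test_that("fleet NOx declines through 2035 in every scenario and electrified fleets approach zero", {
  fl <- generate_fleet(fleet_gen_config(seed = 1))
  rates <- emission_rates(fl)
  profiles <- build_segment_profiles(fl)
  s <- calibrate_survival()
  sales <- sales_trajectory(2020, sum(fl$registrations))
  sp <- scenario_presets()
  years <- 2020:2035
  proj <- lapply(sp, function(x)
    project_nox(x, years, rates, profiles, s, sales = sales))
  for (nm in names(proj)) {
    tot <- proj[[nm]]$total_t
    # the dirtier pre-policy cohorts dominate the 2020s: strict decline
    expect_true(all(diff(tot[years <= 2030]) < 0), info = nm)
    # and 2035 sits far below 2020 in every scenario
    expect_lt(tot[years == 2035], 0.75 * tot[years == 2020])
  }
  # electrified fleets keep falling monotonically all the way
  for (nm in c("Electrified", "ElectrifiedSmallSUV"))
    expect_true(all(diff(proj[[nm]]$total_t) < 0), info = nm)

  # electrified tailpipe NOx is negligible by 2051: a small fraction of
  # the 2020 whole-fleet value once every pre-ban cohort has retired
  el51 <- fleet_annual_nox(sp$Electrified, 2051, rates, profiles, s,
                           sales = sales)
  el20 <- proj$Electrified$total_t[1]
  expect_lt(el51 / el20, 0.01)
})

test_that("NO2 reductions are proportional, clamped and zero for self-comparison", {
  expect_equal(no2_delta(100, 100), 0)
  expect_equal(no2_delta(100, 0), 2.59)
  expect_equal(no2_delta(100, 50), 1.295)
  expect_equal(no2_delta(100, 300), 0)      # clamped at zero
  expect_error(no2_delta(0, 50), "positive")
})

test_that("NO2 reduction series are bounded and non-decreasing for every policy", {
  fl <- generate_fleet(fleet_gen_config(seed = 1))
  rates <- emission_rates(fl)
  profiles <- build_segment_profiles(fl)
  s <- calibrate_survival()
  sales <- sales_trajectory(2020, sum(fl$registrations))
  sp <- scenario_presets()
  years <- 2020:2055
  bau <- project_nox(sp$BAU, years, rates, profiles, s, sales = sales)
  for (nm in setdiff(names(sp), "BAU")) {
    scen <- project_nox(sp[[nm]], years, rates, profiles, s, sales = sales)
    d <- no2_delta_series(bau, scen)
    expect_true(all(d$delta >= 0 & d$delta <= 2.59), info = nm)
    expect_true(all(diff(d$delta) >= -1e-9), info = nm)
  }
})
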