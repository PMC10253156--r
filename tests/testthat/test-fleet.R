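test_that("segment classification splits SUVs by mass and passes others through", {
  expect_equal(classify_segment("J", 2100), "large_suv")
  expect_equal(classify_segment("J", 1400), "small_suv")
  expect_equal(classify_segment("B", 1200), "B")
  # interval boundaries are closed: 1500 and 2000 kg are both medium
  expect_equal(classify_segment(c("J", "J"), c(1500, 2000)),
               c("medium_suv", "medium_suv"))
  expect_equal(classify_segment("J", 1499.9), "small_suv")
  expect_equal(classify_segment("J", 2000.1), "large_suv")
  expect_error(classify_segment("X", 1000), "X")
  expect_error(classify_segment("J", -5), "positive")
})

test_that("SUV sub-classification partitions the J segment", {
  fl <- generate_fleet(fleet_gen_config(seed = 7))
  j <- fl$segment == "J"
  key <- classify_segment(fl$segment, fl$kerb_mass)
  expect_equal(sum(key %in% c("small_suv", "medium_suv", "large_suv")),
               sum(j))
  expect_true(all(key[!j] == fl$segment[!j]))
})

test_that("per-model annual emissions follow the conversion arithmetic", {
  expect_equal(annual_model_co2(100, 1, 10137), 1.0137)
  expect_equal(annual_model_co2(5, 0, 10137), 0)
  expect_equal(annual_model_co2(170, 10000, 15125), 25712.5)
  expect_equal(annual_model_nox(100, 1000, 10137), 1.0137)
  expect_equal(annual_model_nox(0, 5000, 15125), 0)
  expect_equal(annual_model_nox(80, 100000, 15125), 121.0)
  expect_error(annual_model_co2(-1, 1, 1), "non-negative")
  expect_error(annual_model_nox(1, -1, 1), "non-negative")
})

test_that("fuel classes map to the right annual distances", {
  d <- distance_assumptions()
  expect_equal(fuel_distance(c("petrol", "petrol_hybrid", "petrol_phev"), d),
               rep(10137, 3))
  expect_equal(fuel_distance(c("diesel", "diesel_hybrid"), d),
               rep(15125, 2))
  expect_equal(fuel_distance("bev", d), 15180)
  expect_error(fuel_distance("lpg", d), "lpg")
  expect_error(distance_assumptions(petrol = 0), "positive")
})

test_that("segment profiles aggregate totals, means and share ratios", {
  fl <- toy_fleet()
  prof <- suppressWarnings(build_segment_profiles(fl))
  d <- fuel_distance(fl$fuel)
  co2 <- annual_model_co2(fl$co2_wltp, fl$registrations, d)

  # conservation: per-segment mean x count sums to the fleet total
  expect_equal(sum(prof$mean_annual_co2 * prof$n_vehicles), sum(co2))

  # single-record segment: mean equals that record's annual per-vehicle value
  m <- prof[prof$segment_key == "M", ]
  expect_equal(m$mean_annual_co2, co2[6] / fl$registrations[6])
  # M has no NOx-tested records
  expect_true(is.na(m$mean_annual_nox))
  expect_equal(m$n_vehicles_nox, 0)

  # NOx means use only NOx-tested registrations (here the 500 diesels and
  # 200 BEVs of the large-SUV segment; the untested M record is excluded)
  lg <- prof[prof$segment_key == "large_suv", ]
  expect_equal(lg$mean_annual_nox, 1000 * 250 * 500 * 15125 / 1e9 / 700)

  # fleet-weighted mean of the emission-share/registration-share ratio is 1
  expect_equal(sum(prof$co2_registration_ratio * prof$n_vehicles) /
                 sum(prof$n_vehicles), 1)
  ok <- !is.na(prof$nox_registration_ratio)
  expect_equal(sum((prof$nox_registration_ratio * prof$n_vehicles_nox)[ok]) /
                 sum(prof$n_vehicles_nox[ok]), 1)
})

test_that("profile construction warns about empty segments, never silent zeros", {
  w <- capture_warnings(prof <- build_segment_profiles(toy_fleet()))
  expect_true(any(grepl("omitted", w)))
  expect_true(any(grepl("no NOx-tested", w)))
  expect_false("A" %in% prof$segment_key)
})

test_that("scaling registrations scales totals but not per-vehicle means", {
  fl <- toy_fleet()
  fl2 <- fl
  fl2$registrations <- fl$registrations * 3
  p1 <- suppressWarnings(build_segment_profiles(fl))
  p2 <- suppressWarnings(build_segment_profiles(fl2))
  expect_equal(p2$n_vehicles, 3 * p1$n_vehicles)
  expect_equal(p2$mean_annual_co2, p1$mean_annual_co2)
  expect_equal(p2$mean_annual_nox, p1$mean_annual_nox)
  expect_equal(sum(p2$mean_annual_co2 * p2$n_vehicles),
               3 * sum(p1$mean_annual_co2 * p1$n_vehicles))
})

test_that("fleet reader validates and reports offending rows", {
  fl <- toy_fleet()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fleet(fl, path)
  back <- read_fleet(path)
  expect_equal(back$registrations, fl$registrations)
  expect_equal(back$nox_rde, fl$nox_rde)

  bad <- fl
  bad$kerb_mass[3] <- -1
  expect_error(validate_fleet(bad), "rows 3")
  bad <- fl
  bad$co2_wltp[7] <- 10  # BEV with nonzero CO2
  expect_error(validate_fleet(bad), "BEV")
  bad <- fl
  bad$fuel[2] <- "hydrogen"
  expect_error(validate_fleet(bad), "fuel")
  expect_error(validate_fleet(fl[, -3]), "missing columns")
})

test_that("emission rate cells are consistent with segment profiles", {
  fl <- generate_fleet(fleet_gen_config(seed = 3))
  prof <- build_segment_profiles(fl)
  rates <- emission_rates(fl)
  # aggregating cells back to segments reproduces the segment means
  for (sg in c("B", "large_suv", "M")) {
    cells <- rates[rates$segment_key == sg, ]
    expect_equal(sum(cells$co2_t_per_vehicle * cells$count) /
                   sum(cells$count),
                 prof$mean_annual_co2[prof$segment_key == sg])
  }
  expect_equal(sum(rates$count), sum(fl$registrations))
  expect_true(attr(rates, "bev_share") > 0 && attr(rates, "bev_share") < 1)
})
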