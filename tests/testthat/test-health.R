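test_that("relative risk follows the log-linear concentration-response form", {
  expect_equal(relative_risk(0), 1)
  expect_equal(relative_risk(10), 1 / 1.023)
  expect_equal(relative_risk(10), 0.977517, tolerance = 1e-6)
  expect_gt(relative_risk(-5), 1)          # an increase raises risk
  expect_equal(relative_risk(20, exposure_response(1.05)), 1.05^-2)
  expect_error(exposure_response(0), "positive")
})

test_that("the inception lag phases a step change in at the stated anchors", {
  yrs <- 2020:2045
  step <- setNames(rep(2, length(yrs)), yrs)   # step of 2 ug/m3 in 2020
  eff <- lagged_delta(step)
  expect_equal(unname(eff[1]), 0.6)            # 30% in the first year
  expect_equal(unname(eff[5]), 2 * 0.8)        # 80% by year 5
  expect_equal(unname(eff[20]), 2)             # full effect at year 20
  expect_equal(unname(eff[26]), 2)
  expect_true(all(diff(eff) >= -1e-12))
  # no change, no effect
  zero <- setNames(rep(0, 5), 2020:2024)
  expect_equal(unname(lagged_delta(zero)), rep(0, 5))
  # without a lag the series passes through untouched
  expect_equal(lagged_delta(step, lag = NULL), step)
  expect_error(lag_schedule(c(0.3, 0.2, 1)), "non-decreasing")
  expect_error(lag_schedule(c(0.3, 0.9)), "reach 1")
})

test_that("a null concentration change yields exactly zero life years gained", {
  pop <- generate_population()
  d <- setNames(rep(0, 20), 2020:2039)
  res <- life_years_gained(pop, d, end_year = 2060)
  expect_equal(res$total, 0)
  expect_equal(unname(res$by_year), rep(0, length(res$by_year)))
})

test_that("life table agrees with a per-cohort microsimulation oracle", {
  pop <- generate_population()
  end_year <- 2070
  yrs <- 2020:end_year
  delta <- setNames(pmin(2.59, 0.2 * (yrs - 2019)), yrs)  # ramp then flat

  # lag handled outside both engines so the oracle stays independent
  full <- setNames(numeric(end_year - pop$base_year),
                   (pop$base_year + 1):end_year)
  full[names(delta)] <- delta
  eff <- lagged_delta(full)

  got <- life_years_gained(pop, delta, end_year = end_year)
  want <- oracle_life_years(pop, eff, end_year = end_year)
  expect_equal(got$total, want, tolerance = 1e-6)
  expect_gt(got$total, 0)

  # and without any lag
  got_nolag <- life_years_gained(pop, delta, lag = NULL,
                                 end_year = end_year)
  want_nolag <- oracle_life_years(pop, full, end_year = end_year)
  expect_equal(got_nolag$total, want_nolag, tolerance = 1e-6)
})

test_that("hazards below the minimum age are never modified", {
  # a population of under-30s only, followed for too short a span for
  # anyone to cross the age threshold: no life years can be gained
  ages <- 0:20
  df <- rbind(
    data.frame(sex = "female", age = ages, population = 1000,
               deaths = 10),
    data.frame(sex = "male", age = ages, population = 1000, deaths = 10))
  pop <- life_table_population(df, base_year = 2019, annual_births = 2000)
  d <- setNames(rep(2.59, 5), 2020:2024)
  res <- life_years_gained(pop, d, end_year = 2027)
  expect_equal(res$total, 0)
})

test_that("life years gained grow with the coefficient and the reduction size", {
  pop <- generate_population()
  yrs <- 2020:2050
  d1 <- setNames(rep(1, length(yrs)), yrs)
  d2 <- setNames(rep(2, length(yrs)), yrs)
  ly <- function(d, rr) life_years_gained(
    pop, d, er = exposure_response(rr), end_year = 2080)$total
  weak <- ly(d1, 1.008); mid <- ly(d1, 1.023); strong <- ly(d1, 1.037)
  expect_lt(weak, mid); expect_lt(mid, strong)
  expect_lt(mid, ly(d2, 1.023))
})

test_that("the inception lag costs a few percent of the life years", {
  pop <- generate_population()
  yrs <- 2020:2055
  delta <- setNames(pmin(2.59, 0.13 * (yrs - 2019)), yrs)
  lagged <- life_years_gained(pop, delta, end_year = 2126)$total
  unlagged <- life_years_gained(pop, delta, lag = NULL,
                                end_year = 2126)$total
  expect_gt(unlagged, lagged)
  loss <- (unlagged - lagged) / unlagged
  expect_gt(loss, 0.02)
  expect_lt(loss, 0.08)
})

test_that("excessive risk increases are rejected, not clamped", {
  df <- rbind(
    data.frame(sex = "female", age = 0:40, population = 1000,
               deaths = c(rep(10, 40), 960)),
    data.frame(sex = "male", age = 0:40, population = 1000,
               deaths = c(rep(10, 40), 960)))
  pop <- life_table_population(df, base_year = 2019, annual_births = 2000)
  worse <- setNames(rep(-30, 10), 2020:2029)  # large increase in NO2
  expect_error(life_years_gained(pop, worse, lag = NULL, end_year = 2030),
               "exceeds 1")
})

test_that("valuation is linear in the VOLY and discounts the stream", {
  ly <- setNames(c(100, 100, 100), 2020:2022)
  expect_equal(value_life_years(ly, valuation_params(60000, 0)),
               60000 * 300)
  v1 <- value_life_years(ly, valuation_params(60000, 0.015))
  v2 <- value_life_years(ly, valuation_params(30000, 0.015))
  expect_equal(v1, 2 * v2)
  expect_equal(v1, 60000 * sum(100 / 1.015^(0:2)))
  v_high <- value_life_years(ly, valuation_params(60000, 0.035))
  expect_lt(v_high, v1)
  expect_error(valuation_params(voly = -1), "positive")
})

test_that("the sensitivity grid is coherent across its axes", {
  pop <- generate_population()
  yrs <- 2020:2045
  delta <- setNames(pmin(2.59, 0.15 * (yrs - 2019)), yrs)
  grid <- sensitivity_grid(pop, delta, end_year = 2080)
  expect_equal(nrow(grid), 12)
  # monotone increasing across the coefficient axis
  for (v in unique(grid$voly))
    for (r in unique(grid$discount_rate)) {
      sub <- grid[grid$voly == v & grid$discount_rate == r, ]
      sub <- sub[order(sub$coefficient), ]
      expect_true(all(diff(sub$value_gbp) > 0))
      expect_true(all(diff(sub$life_years) > 0))
    }
  # VOLY rows are related by the exact ratio of the VOLYs
  for (r in unique(grid$discount_rate))
    for (cf in unique(grid$coefficient)) {
      v20 <- grid$value_gbp[grid$voly == 20000 & grid$discount_rate == r &
                              grid$coefficient == cf]
      v60 <- grid$value_gbp[grid$voly == 60000 & grid$discount_rate == r &
                              grid$coefficient == cf]
      expect_equal(v60 / v20, 3)
    }
  # a higher discount rate always lowers the value
  for (v in unique(grid$voly))
    for (cf in unique(grid$coefficient)) {
      lo <- grid$value_gbp[grid$voly == v & grid$coefficient == cf &
                             grid$discount_rate == 0.015]
      hi <- grid$value_gbp[grid$voly == v & grid$coefficient == cf &
                             grid$discount_rate == 0.035]
      expect_lt(hi, lo)
    }
})
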