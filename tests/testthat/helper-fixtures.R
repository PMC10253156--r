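# Fixtures built in code: tiny deterministic fleets and populations used
# across the test files.

# A hand-sized fleet: known registrations, segments and emission values.
toy_fleet <- function() {
  data.frame(
    model_id = c("b1", "b2", "j_small", "j_med", "j_large", "m1", "ev1"),
    registrations = c(1000, 3000, 2000, 1500, 500, 800, 200),
    segment = c("B", "B", "J", "J", "J", "M", "J"),
    fuel = c("petrol", "petrol", "petrol", "diesel", "diesel",
             "diesel", "bev"),
    kerb_mass = c(1100, 1200, 1400, 1700, 2200, 1900, 2100),
    wltp_test_mass = c(1200, 1300, 1500, 1800, 2300, 2000, 2200),
    engine_capacity = c(1000, 1200, 1300, 1900, 2900, 2000, 0),
    wheelbase = c(2500, 2550, 2600, 2700, 2900, 2950, 2900),
    co2_wltp = c(120, 130, 150, 170, 220, 180, 0),
    nox_rde = c(40, 50, 60, 150, 250, NA, 0),
    stringsAsFactors = FALSE
  )
}

# Flat survival for three years then gone: S = 1, 1, 1, 0.
flat_schedule <- function(years_full = 3) {
  survival_schedule(c(rep(1, years_full), 0))
}

# A small population with constant hazard, handy for closed-form checks.
const_hazard_population <- function(q = 0.01, max_age = 30,
                                    births = 1000, base_year = 2019) {
  ages <- 0:max_age
  per_sex <- births / 2
  pop <- per_sex * cumprod(c(1, rep(1 - q, max_age)))
  df <- rbind(
    data.frame(sex = "female", age = ages, population = pop,
               deaths = pop * q),
    data.frame(sex = "male", age = ages, population = pop,
               deaths = pop * q)
  )
  life_table_population(df, base_year = base_year, annual_births = births)
}

# Independent microsimulation oracle for the life table: explicit
# survival-product bookkeeping per birth cohort, one cohort at a time.
# rr_fun(year) returns the hazard multiplier applied at ages >= min_age.
oracle_person_years <- function(pop, years, rr_fun, min_age = 30) {
  total <- stats::setNames(numeric(length(years)), years)
  for (sx in names(pop$sexes)) {
    p <- pop$sexes[[sx]]
    max_age <- p$max_age
    births <- pop$annual_births / length(pop$sexes)
    # existing cohorts: one per age in the base-year snapshot
    for (a0 in 0:max_age) {
      alive <- p$population[a0 + 1]
      for (i in seq_along(years)) {
        age <- a0 + i
        if (age > max_age) break
        q <- p$hazard[age + 1]
        if (age >= min_age) q <- q * rr_fun(years[i])
        alive <- alive * (1 - q)
        total[i] <- total[i] + alive
      }
    }
    # future birth cohorts: born in each simulated year at age 0
    for (b in seq_along(years)) {
      alive <- births
      for (i in b:length(years)) {
        age <- i - b
        if (age > max_age) break
        q <- p$hazard[age + 1]
        if (age >= min_age) q <- q * rr_fun(years[i])
        alive <- alive * (1 - q)
        total[i] <- total[i] + alive
      }
    }
  }
  total
}

# Life years gained according to the oracle, for a given delta series
# (already lagged or not, handled by caller through eff).
oracle_life_years <- function(pop, eff_by_year, er = exposure_response(),
                              end_year) {
  years <- (pop$base_year + 1):end_year
  eff <- stats::setNames(numeric(length(years)), years)
  known <- intersect(names(eff_by_year), as.character(years))
  eff[known] <- eff_by_year[known]
  last <- max(as.integer(names(eff_by_year)))
  eff[years > last] <- eff_by_year[as.character(last)]
  rr <- stats::setNames(relative_risk(eff, er), years)
  base <- oracle_person_years(pop, years, function(y) 1, er$min_age)
  imp <- oracle_person_years(pop, years, function(y) rr[[as.character(y)]],
                             er$min_age)
  sum(imp - base)
}
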