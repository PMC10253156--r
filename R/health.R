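## Life-table health impact assessment: converts a time series of NO2
## reductions into life years gained, via a log-linear
## concentration-response function applied to all-cause mortality hazards
## at ages 30 and above, with a distributed inception lag, and values the
## stream at a discounted value per life year.

#' Life table population
#'
#' Baseline population and death counts by sex and single year of age,
#' from which annual mortality hazards are derived (deaths over
#' population). Hazards for ages 90 and above are pooled: every age from
#' 90 to the maximum shares the group's aggregate hazard. Births,
#' population and hazards are held constant in future years.
#'
#' @param data data.frame with columns `sex` ("female"/"male"), `age`
#'   (consecutive integers from 0 per sex), `population`, `deaths`.
#' @param base_year calendar year the snapshot represents.
#' @param annual_births total births per year (split evenly by sex); if
#'   `NULL`, twice each sex's age-0 population divided by its age-0
#'   survival is approximated by the age-0 population itself.
#' @return a `life_table_population` object.
#' @export
life_table_population <- function(data, base_year = 2019,
                                  annual_births = NULL) {
  need <- c("sex", "age", "population", "deaths")
  if (!all(need %in% names(data)))
    stop("population table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sexes <- sort(unique(data$sex))
  if (!all(sexes %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  data <- data[order(data$sex, data$age), ]
  per_sex <- lapply(sexes, function(sx) {
    d <- data[data$sex == sx, ]
    if (!identical(as.integer(d$age), seq_len(nrow(d)) - 1L))
      stop("ages for ", sx, " must be consecutive integers from 0",
           call. = FALSE)
    if (any(d$population <= 0))
      stop("population must be positive at every age (", sx, ")",
           call. = FALSE)
    if (any(d$deaths < 0))
      stop("deaths must be non-negative (", sx, ")", call. = FALSE)
    q <- d$deaths / d$population
    bad <- which(q >= 1)
    if (length(bad))
      stop("hazard >= 1 at age ", d$age[bad[1]], " for ", sx,
           call. = FALSE)
    # pooled hazard for ages 90+
    old <- d$age >= 90
    if (any(old))
      q[old] <- sum(d$deaths[old]) / sum(d$population[old])
    list(population = d$population, deaths = d$deaths, hazard = q,
         max_age = max(d$age))
  })
  names(per_sex) <- sexes
  if (is.null(annual_births))
    annual_births <- sum(vapply(per_sex, function(p) p$population[1],
                                numeric(1)))
  structure(list(sexes = per_sex, base_year = as.integer(base_year),
                 annual_births = annual_births),
            class = "life_table_population")
}

#' @export
print.life_table_population <- function(x, ...) {
  tot <- sum(vapply(x$sexes, function(p) sum(p$population), numeric(1)))
  cat(sprintf("Life table population, base year %d\n", x$base_year))
  cat(sprintf("  total population %.2f million, %s births/year, ages 0-%d\n",
              tot / 1e6, format(x$annual_births, big.mark = ","),
              x$sexes[[1]]$max_age))
  invisible(x)
}

#' Read a population file
#'
#' Comma-separated with header `sex,age,population,deaths`.
#'
#' @param path file path.
#' @inheritParams life_table_population
#' @return a `life_table_population`.
#' @export
read_population <- function(path, base_year = 2019,
                            annual_births = NULL) {
  life_table_population(utils::read.csv(path, stringsAsFactors = FALSE),
                        base_year = base_year,
                        annual_births = annual_births)
}

#' Write a population file
#'
#' @param pop a `life_table_population`.
#' @param path file path.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "life_table_population"))
  rows <- lapply(names(pop$sexes), function(sx) {
    p <- pop$sexes[[sx]]
    data.frame(sex = sx, age = 0:p$max_age, population = p$population,
               deaths = p$deaths)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Concentration-response function for NO2 mortality
#'
#' Relative risk of all-cause mortality per 10 micrograms per cubic metre
#' of NO2 (central 1.023, 95 percent CI 1.008-1.037), applied at ages 30
#' and above.
#'
#' @param rr_per_10ug relative risk per 10 ug/m3 increase.
#' @param min_age youngest age at which the hazard is modified.
#' @return an `exposure_response` object.
#' @export
exposure_response <- function(rr_per_10ug = 1.023, min_age = 30) {
  if (rr_per_10ug <= 0)
    stop("rr_per_10ug must be positive", call. = FALSE)
  structure(list(rr_per_10ug = rr_per_10ug, min_age = min_age),
            class = "exposure_response")
}

#' Relative risk for a concentration change
#'
#' `RR^(-delta/10)`: below 1 for a reduction (`delta > 0`), above 1 for an
#' increase.
#'
#' @param delta NO2 reduction, micrograms per cubic metre (negative for
#'   an increase).
#' @param er an [exposure_response()] object.
#' @return dimensionless relative risk.
#' @export
relative_risk <- function(delta, er = exposure_response()) {
  stopifnot(inherits(er, "exposure_response"))
  er$rr_per_10ug^(-delta / 10)
}

#' Inception lag schedule
#'
#' Cumulative fraction of the mortality effect realised by years since a
#' concentration change: 30 percent in the first year, a further 50
#' percent spread evenly over years 2-5, and the remaining 20 percent
#' spread evenly over years 6-20 (the full effect from year 20 onward).
#'
#' @param cumulative optional replacement vector of cumulative fractions
#'   for years 1..n since change; must be non-decreasing and end at 1.
#' @return a `lag_schedule` object.
#' @export
lag_schedule <- function(cumulative = NULL) {
  if (is.null(cumulative))
    cumulative <- cumsum(c(0.30, rep(0.50 / 4, 4), rep(0.20 / 15, 15)))
  if (any(diff(cumulative) < -1e-12))
    stop("cumulative lag fractions must be non-decreasing", call. = FALSE)
  if (abs(cumulative[length(cumulative)] - 1) > 1e-9)
    stop("cumulative lag fractions must reach 1", call. = FALSE)
  structure(list(cumulative = cumulative), class = "lag_schedule")
}

#' Effective concentration change after the inception lag
#'
#' Decomposes the reduction series into yearly increments and phases each
#' increment in according to the cumulative lag schedule, so a single step
#' change reaches 30 percent of its effect in its first year and 100
#' percent from year 20.
#'
#' @param delta_series named numeric vector of NO2 reductions by calendar
#'   year (consecutive years).
#' @param lag a [lag_schedule()], or `NULL` for no lag (effect immediate).
#' @return named numeric vector of effective reductions, same years.
#' @export
lagged_delta <- function(delta_series, lag = lag_schedule()) {
  yrs <- as.integer(names(delta_series))
  if (any(is.na(yrs)) || (length(yrs) > 1 && any(diff(yrs) != 1)))
    stop("delta_series must be named by consecutive years", call. = FALSE)
  if (is.null(lag)) return(delta_series)
  L <- lag$cumulative
  n <- length(delta_series)
  inc <- diff(c(0, as.numeric(delta_series)))
  eff <- numeric(n)
  for (i in seq_len(n)) {
    if (inc[i] == 0) next
    since <- seq_len(n - i + 1)           # years since this increment
    w <- L[pmin(since, length(L))]
    eff[i:n] <- eff[i:n] + inc[i] * w
  }
  stats::setNames(eff, yrs)
}

# Forward life-table engine for one sex. `alive` holds the end-of-year
# population by age attained that year; each simulated year everyone ages
# one year (the oldest age exits), newborns enter at age 0, and the
# (possibly risk-scaled) annual death probability of the attained age is
# applied. Person-years accrue as the end-of-year population.
# rr_by_year: named RR multipliers applied at ages >= min_age.
.project_person_years <- function(p, births, years, rr_by_year, min_age) {
  n_age <- p$max_age + 1L
  mod <- (seq_len(n_age) - 1L) >= min_age
  alive <- p$population                   # base-year end-of-year population
  py <- stats::setNames(numeric(length(years)), years)
  for (i in seq_along(years)) {
    q <- p$hazard
    rr <- rr_by_year[[as.character(years[i])]]
    if (!is.null(rr) && rr != 1) {
      q[mod] <- q[mod] * rr
      if (any(q > 1))
        stop("modified hazard exceeds 1 at age ",
             which(q > 1)[1] - 1L, " in ", years[i], call. = FALSE)
    }
    shifted <- c(births, alive[-n_age])
    alive <- shifted * (1 - q)
    py[i] <- sum(alive)
  }
  py
}

#' Life years gained from an NO2 reduction series
#'
#' Runs the life table twice per sex — baseline hazards, and hazards
#' scaled by the concentration-response relative risk of the lagged
#' effective reduction, at ages of 30 and above — from the population base
#' year to `end_year`, with births, baseline population and hazards held
#' constant. Life years accrue at the end of each year (end-of-year
#' population convention); the difference in person-years between the
#' impacted and baseline runs is the gain. Reductions before the first
#' series year are zero; the last value is held constant to `end_year`.
#'
#' @param pop a [life_table_population()].
#' @param delta_series named numeric vector (by calendar year) of NO2
#'   reductions versus business as usual, micrograms per cubic metre.
#' @param er an [exposure_response()] object.
#' @param lag a [lag_schedule()], or `NULL` to apply effects immediately.
#' @param end_year last year of follow-up.
#' @return an `hia_result` list: `total` life years gained, `by_year`
#'   (named vector), `end_year`.
#' @export
life_years_gained <- function(pop, delta_series, er = exposure_response(),
                              lag = lag_schedule(), end_year = 2126) {
  stopifnot(inherits(pop, "life_table_population"),
            end_year > pop$base_year)
  yrs <- as.integer(names(delta_series))
  if (any(is.na(yrs)))
    stop("delta_series must be named by calendar years", call. = FALSE)
  sim_years <- (pop$base_year + 1L):end_year
  full <- stats::setNames(numeric(length(sim_years)), sim_years)
  known <- intersect(sim_years, yrs)
  full[as.character(known)] <- delta_series[as.character(known)]
  if (max(yrs) < end_year)
    full[sim_years > max(yrs)] <- delta_series[as.character(max(yrs))]
  eff <- lagged_delta(full, lag)
  rr <- relative_risk(eff, er)
  rr_by_year <- as.list(rr)

  births_per_sex <- pop$annual_births / length(pop$sexes)
  by_year <- stats::setNames(numeric(length(sim_years)), sim_years)
  for (p in pop$sexes) {
    base <- .project_person_years(p, births_per_sex, sim_years,
                                  list(), er$min_age)
    impacted <- .project_person_years(p, births_per_sex, sim_years,
                                      rr_by_year, er$min_age)
    by_year <- by_year + (impacted - base)
  }
  structure(list(total = sum(by_year), by_year = by_year,
                 end_year = end_year),
            class = "hia_result")
}

#' @export
print.hia_result <- function(x, ...) {
  cat(sprintf("Life years gained by %d: %.0f\n", x$end_year, x$total))
  invisible(x)
}

#' Valuation parameters for life years
#'
#' @param voly value of a life year, GBP.
#' @param discount_rate annual discount rate.
#' @return a `valuation_params` object.
#' @export
valuation_params <- function(voly = 60000, discount_rate = 0.015) {
  if (voly <= 0) stop("voly must be positive", call. = FALSE)
  if (discount_rate < 0)
    stop("discount_rate must be non-negative", call. = FALSE)
  structure(list(voly = voly, discount_rate = discount_rate),
            class = "valuation_params")
}

#' Discounted monetary value of a life-year stream
#'
#' `sum ly(t) * VOLY * (1 + r)^-(t - base_year)`.
#'
#' @param ly_by_year named numeric vector of life years by calendar year
#'   (e.g. the `by_year` element of an `hia_result`).
#' @param params a [valuation_params()] object.
#' @param base_year discounting reference year (policy start).
#' @return value in GBP.
#' @export
value_life_years <- function(ly_by_year, params = valuation_params(),
                             base_year = 2020) {
  yrs <- as.integer(names(ly_by_year))
  if (any(is.na(yrs)))
    stop("ly_by_year must be named by calendar years", call. = FALSE)
  sum(ly_by_year * params$voly *
        (1 + params$discount_rate)^(-(yrs - base_year)))
}

#' Sensitivity grid over valuation and concentration-response choices
#'
#' Recomputes life years gained and their value for every combination of
#' value-of-life-year, discount rate and concentration-response
#' coefficient, all through the same life-table machinery.
#'
#' @inheritParams life_years_gained
#' @param volys values of a life year, GBP.
#' @param rates discount rates.
#' @param coefficients relative risks per 10 micrograms per cubic metre.
#' @param base_year discounting reference year.
#' @return data.frame `voly`, `discount_rate`, `coefficient`,
#'   `life_years`, `value_gbp`.
#' @export
sensitivity_grid <- function(pop, delta_series,
                             volys = c(20000, 60000),
                             rates = c(0.015, 0.035),
                             coefficients = c(1.008, 1.023, 1.037),
                             lag = lag_schedule(), end_year = 2126,
                             base_year = 2020) {
  runs <- lapply(coefficients, function(cf)
    life_years_gained(pop, delta_series,
                      er = exposure_response(rr_per_10ug = cf),
                      lag = lag, end_year = end_year))
  grid <- expand.grid(voly = volys, discount_rate = rates,
                      coefficient = coefficients,
                      KEEP.OUT.ATTRS = FALSE)
  grid$life_years <- vapply(seq_len(nrow(grid)), function(i)
    runs[[match(grid$coefficient[i], coefficients)]]$total, numeric(1))
  grid$value_gbp <- vapply(seq_len(nrow(grid)), function(i) {
    run <- runs[[match(grid$coefficient[i], coefficients)]]
    value_life_years(run$by_year,
                     valuation_params(grid$voly[i], grid$discount_rate[i]),
                     base_year)
  }, numeric(1))
  grid
}
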