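## CO2 projection: annual and cumulative emissions from post-2020 sales
## cohorts, including grid-charging emissions for BEVs, and carbon
## valuation at marginal abatement cost prices.

#' Grid carbon intensity trajectory and BEV energy assumptions
#'
#' Mean annual carbon intensity of the electricity grid by calendar year,
#' linearly interpolated between anchor years and held constant after the
#' last anchor. The default trajectory declines steeply to the mid-2030s,
#' emulating a power sector that is nearly decarbonised by 2035, then
#' stays at a few g/kWh. BEVs are assumed to achieve 6.5 km/kWh and drive
#' 15,180 km per year.
#'
#' @param anchors named numeric vector, gCO2e/kWh by year.
#' @param bev_efficiency km per kWh.
#' @param bev_distance annual km per BEV.
#' @return a `grid_intensity` object.
#' @export
grid_intensity_series <- function(anchors = c("2020" = 180, "2025" = 100,
                                              "2030" = 40, "2035" = 5,
                                              "2050" = 2),
                                  bev_efficiency = 6.5,
                                  bev_distance = 15180) {
  yr <- as.integer(names(anchors))
  if (any(is.na(yr)) || is.unsorted(yr, strictly = TRUE))
    stop("anchors must be named by strictly increasing years",
         call. = FALSE)
  if (any(anchors < 0))
    stop("grid intensity must be non-negative", call. = FALSE)
  if (bev_efficiency <= 0)
    stop("bev_efficiency must be positive", call. = FALSE)
  structure(list(anchor_years = yr, anchor_values = as.numeric(anchors),
                 bev_efficiency = bev_efficiency,
                 bev_distance = bev_distance),
            class = "grid_intensity")
}

#' Grid carbon intensity in a calendar year
#'
#' @param grid a `grid_intensity` object.
#' @param year calendar year(s).
#' @return gCO2e/kWh.
#' @export
grid_intensity <- function(grid, year) {
  stopifnot(inherits(grid, "grid_intensity"))
  stats::approx(grid$anchor_years, grid$anchor_values,
                xout = pmin(pmax(year, min(grid$anchor_years)),
                            max(grid$anchor_years)),
                rule = 2)$y
}

#' Annual charging emissions per BEV
#'
#' Energy used per year (distance over efficiency, kWh) times the grid
#' carbon intensity, in tonnes CO2e per vehicle per year.
#'
#' @param intensity grid carbon intensity, gCO2e/kWh.
#' @param grid a [grid_intensity_series()] object (supplies efficiency and
#'   distance).
#' @return tonnes CO2e per vehicle per year.
#' @export
bev_annual_co2 <- function(intensity, grid = grid_intensity_series()) {
  stopifnot(inherits(grid, "grid_intensity"))
  if (any(intensity < 0))
    stop("intensity must be non-negative", call. = FALSE)
  (grid$bev_distance / grid$bev_efficiency) * intensity / 1e6
}

#' Lifetime charging emissions per BEV of one cohort
#'
#' Sum of annual charging emissions over the vehicle's service life (to
#' the horizon year at the latest), each year weighted by the fraction of
#' the cohort still in service.
#'
#' @param cohort_year registration year.
#' @param horizon_year last calendar year counted (inclusive).
#' @param schedule a `survival_schedule`.
#' @param grid a [grid_intensity_series()] object.
#' @return tonnes CO2e per vehicle registered.
#' @export
bev_lifetime_co2 <- function(cohort_year, horizon_year, schedule, grid) {
  if (horizon_year < cohort_year)
    stop("horizon_year must not precede cohort_year", call. = FALSE)
  ages <- 0:min(schedule$max_age, horizon_year - cohort_year)
  sum(surviving_fraction(schedule, ages) *
        bev_annual_co2(grid_intensity(grid, cohort_year + ages), grid))
}

# Per-vehicle annual CO2 for a composition's cells in a calendar year:
# ICE cells use the base-year per-vehicle rate, plug-in hybrids the
# fleet-wide plug-in mean, BEVs the grid model for that year.
.cell_co2_rate <- function(cells, rates, grid, year) {
  key <- paste(cells$segment_key, cells$fuel)
  rate_key <- paste(rates$segment_key, rates$fuel)
  out <- rates$co2_t_per_vehicle[match(key, rate_key)]
  phev <- cells$fuel == "petrol_phev"
  out[phev & is.na(out)] <- attr(rates, "phev_co2")
  bev <- cells$fuel == "bev"
  out[bev] <- bev_annual_co2(grid_intensity(grid, year), grid)
  if (anyNA(out))
    stop("no base-year emission rate for cells: ",
         paste(key[is.na(out)], collapse = "; "), call. = FALSE)
  out
}

#' Project annual and cumulative CO2 for a scenario
#'
#' For every sales cohort from the base year to the horizon and every
#' calendar year of its service life up to the horizon (inclusive), sums
#' surviving-count-weighted per-vehicle emissions: internal-combustion
#' cells at their base-year per-vehicle rates, BEVs at the grid model of
#' the calendar year.
#'
#' @param spec a `scenario_spec`.
#' @param horizon last calendar year counted (e.g. 2035 or 2050).
#' @param rates an [emission_rates()] table for the base-year fleet.
#' @param schedule a `survival_schedule`.
#' @param grid a [grid_intensity_series()] object.
#' @param sales a [sales_trajectory()] function.
#' @param base_year first modelled year.
#' @return a list of class `co2_projection`: `cumulative_mt` (total),
#'   `bev_mt` (grid-charging component), `annual_mt` (fleet emissions of
#'   post-policy cohorts by calendar year), `annual_new_mt` (first-year
#'   emissions of each year's cohort), `scenario`, `horizon`.
#' @export
project_co2 <- function(spec, horizon, rates, schedule,
                        grid = grid_intensity_series(),
                        sales = sales_trajectory(), base_year = 2020) {
  stopifnot(inherits(spec, "scenario_spec"), horizon >= base_year)
  years <- base_year:horizon
  annual <- stats::setNames(numeric(length(years)), years)
  annual_new <- annual
  bev_total <- 0
  total <- 0
  base_comp <- rates[, c("segment_key", "fuel", "count")]
  for (cy in years) {
    cells <- compose_cohort(spec, cy, base_comp, sales, base_year)
    for (t in cy:horizon) {
      sf <- surviving_fraction(schedule, t - cy)
      if (sf == 0) break
      r <- .cell_co2_rate(cells, rates, grid, t)
      em <- sum(cells$count * sf * r)
      total <- total + em
      annual[as.character(t)] <- annual[as.character(t)] + em
      bev_total <- bev_total +
        sum((cells$count * sf * r)[cells$fuel == "bev"])
      if (t == cy) annual_new[as.character(t)] <- em
    }
  }
  structure(list(cumulative_mt = total / 1e6, bev_mt = bev_total / 1e6,
                 annual_mt = annual / 1e6, annual_new_mt = annual_new / 1e6,
                 scenario = spec$name, horizon = horizon),
            class = "co2_projection")
}

#' @export
print.co2_projection <- function(x, ...) {
  cat(sprintf("CO2 projection, scenario %s to %d: %.1f Mt cumulative (%.2f Mt from BEV charging)\n",
              x$scenario, x$horizon, x$cumulative_mt, x$bev_mt))
  invisible(x)
}

#' Cumulative CO2 for a scenario and horizon
#'
#' Convenience wrapper around [project_co2()] returning megatonnes.
#'
#' @inheritParams project_co2
#' @return cumulative emissions, Mt.
#' @export
cumulative_co2 <- function(spec, horizon, rates, schedule,
                           grid = grid_intensity_series(),
                           sales = sales_trajectory(), base_year = 2020) {
  project_co2(spec, horizon, rates, schedule, grid, sales,
              base_year)$cumulative_mt
}

#' Value an emission saving at a carbon price
#'
#' @param saving_mt emission saving, Mt CO2e.
#' @param price_gbp_t marginal abatement cost, GBP per tonne.
#' @return value in GBP billions.
#' @export
value_carbon <- function(saving_mt, price_gbp_t) {
  if (any(price_gbp_t <= 0))
    stop("carbon price must be positive", call. = FALSE)
  .check_nonneg(saving_mt, "saving_mt")
  saving_mt * price_gbp_t / 1000
}

#' Default marginal abatement cost prices (GBP/tonne CO2e)
#'
#' Low/central/high prices for valuation at the 2035 and 2050 horizons.
#'
#' @return list with elements `"2035"` and `"2050"`.
#' @export
carbon_prices <- function() {
  list("2035" = c(low = 151.1, central = 302.3, high = 453.4),
       "2050" = c(low = 189.2, central = 378.3, high = 567.5))
}

#' Percentage change relative to a baseline
#'
#' @param x value(s).
#' @param baseline baseline value.
#' @return percentage change, `100 * (x - baseline) / baseline`.
#' @export
percent_change <- function(x, baseline) {
  if (any(baseline == 0)) stop("baseline must be non-zero", call. = FALSE)
  100 * (x - baseline) / baseline
}
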