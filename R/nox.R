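## Whole-fleet NOx projection: legacy (pre-policy) vehicles emitting at
## the type-approval limit of their registration era, plus post-policy
## cohorts emitting at base-year per-vehicle rates, and the translation of
## fleet NOx changes into urban background NO2 reductions relative to
## business as usual.

#' Regulatory NOx emission limits by fuel and registration year
#'
#' Step table of the maximum permitted NOx (mg/km) by fuel and first
#' registration year, following the European emission-standard tiers.
#' Pre-2001 rows are type-approval-era proxies. Fully overridable: supply
#' any data.frame with columns `fuel`, `from_year`, `limit_mg_km`.
#'
#' @param table optional replacement limit table.
#' @return a `euro_limits` data.frame.
#' @export
euro_nox_limits <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      fuel = rep(c("diesel", "petrol"), c(5, 4)),
      from_year = c(-Inf, 2001, 2006, 2011, 2015,
                    -Inf, 2001, 2006, 2011),
      limit_mg_km = c(900, 500, 250, 180, 80,
                      500, 150, 80, 60)
    )
  }
  need <- c("fuel", "from_year", "limit_mg_km")
  if (!all(need %in% names(table)))
    stop("limit table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$limit_mg_km <= 0))
    stop("NOx limits must be positive", call. = FALSE)
  table <- table[order(table$fuel, table$from_year), ]
  structure(table, class = c("euro_limits", "data.frame"))
}

#' Look up the NOx limit for a fuel and registration year
#'
#' @param limits a [euro_nox_limits()] table.
#' @param fuel fuel name(s) matching the table's `fuel` column.
#' @param reg_year first registration year(s).
#' @return mg/km limit(s).
#' @export
nox_limit <- function(limits, fuel, reg_year) {
  stopifnot(inherits(limits, "euro_limits"))
  n <- max(length(fuel), length(reg_year))
  fuel <- rep_len(fuel, n); reg_year <- rep_len(reg_year, n)
  vapply(seq_len(n), function(i) {
    rows <- limits[limits$fuel == fuel[i] &
                     limits$from_year <= reg_year[i], , drop = FALSE]
    if (nrow(rows) == 0)
      stop("no NOx limit for fuel '", fuel[i], "', registration year ",
           reg_year[i], call. = FALSE)
    rows$limit_mg_km[which.max(rows$from_year)]
  }, numeric(1))
}

#' Default legacy (pre-policy) fleet composition
#'
#' Constant historical sales with a fixed diesel share, as the real
#' pre-policy registration series is not part of the inputs. One row per
#' registration year and fuel.
#'
#' @param years registration years covered.
#' @param annual_sales vehicles registered per year.
#' @param diesel_share fraction of each historical cohort that is diesel
#'   (the remainder is petrol).
#' @return data.frame `reg_year`, `fuel`, `count`.
#' @export
legacy_fleet <- function(years = 1995:2019, annual_sales = 2.5e6,
                         diesel_share = 0.45) {
  stopifnot(annual_sales > 0, diesel_share >= 0, diesel_share <= 1)
  data.frame(
    reg_year = rep(years, each = 2),
    fuel = rep(c("diesel", "petrol"), length(years)),
    count = rep(annual_sales * c(diesel_share, 1 - diesel_share),
                length(years))
  )
}

#' Annual NOx from the legacy fleet in one calendar year
#'
#' Each pre-policy cohort emits at the regulatory limit of its
#' registration era, at the fuel's annual distance, weighted by the
#' fraction still in service.
#'
#' @param year calendar year.
#' @param legacy a [legacy_fleet()] data.frame.
#' @param limits a [euro_nox_limits()] table.
#' @param distances a [distance_assumptions()] object.
#' @param schedule a `survival_schedule`.
#' @return tonnes NOx per year.
#' @export
legacy_fleet_nox <- function(year, legacy, limits = euro_nox_limits(),
                             distances = distance_assumptions(),
                             schedule) {
  stopifnot(all(c("reg_year", "fuel", "count") %in% names(legacy)))
  age <- year - legacy$reg_year
  if (any(age < 0))
    stop("legacy cohorts must be registered before the evaluation year",
         call. = FALSE)
  alive <- legacy$count * surviving_fraction(schedule, age)
  lim <- nox_limit(limits, legacy$fuel, legacy$reg_year)
  dist <- fuel_distance(legacy$fuel, distances)
  sum(annual_model_nox(lim, alive, dist))
}

# Per-vehicle annual NOx (kg) for a composition's cells: base-year cell
# rates; plug-in hybrids fall back to the fleet-wide plug-in mean, any
# other cell without NOx data falls back to its segment's mean; BEVs 0.
.cell_nox_rate <- function(cells, rates, profiles) {
  key <- paste(cells$segment_key, cells$fuel)
  rate_key <- paste(rates$segment_key, rates$fuel)
  out <- rates$nox_kg_per_vehicle[match(key, rate_key)]
  out[cells$fuel == "bev"] <- 0
  phev <- cells$fuel == "petrol_phev"
  out[phev & is.na(out)] <- attr(rates, "phev_nox")
  na <- is.na(out)
  if (any(na)) {
    seg_mean <- profiles$mean_annual_nox[match(cells$segment_key[na],
                                               profiles$segment_key)]
    if (anyNA(seg_mean))
      stop("no NOx rate available for cells: ",
           paste(key[na][is.na(seg_mean)], collapse = "; "),
           call. = FALSE)
    warning("cells without NOx data use their segment mean: ",
            paste(key[na], collapse = "; "), call. = FALSE)
    out[na] <- seg_mean
  }
  out
}

#' Whole-fleet annual NOx under a scenario
#'
#' Legacy-fleet emissions plus the surviving post-policy cohorts. New
#' internal-combustion vehicles are assumed to keep emitting at base-year
#' per-vehicle rates indefinitely.
#'
#' @param spec a `scenario_spec`.
#' @param year calendar year (>= base year).
#' @param rates an [emission_rates()] table.
#' @param profiles a [build_segment_profiles()] table (NOx fallback).
#' @param schedule a `survival_schedule`.
#' @param legacy a [legacy_fleet()] data.frame.
#' @param limits a [euro_nox_limits()] table.
#' @param distances a [distance_assumptions()] object.
#' @param sales a [sales_trajectory()] function.
#' @param base_year first modelled year.
#' @return tonnes NOx in that year.
#' @export
fleet_annual_nox <- function(spec, year, rates, profiles, schedule,
                             legacy = legacy_fleet(),
                             limits = euro_nox_limits(),
                             distances = distance_assumptions(),
                             sales = sales_trajectory(),
                             base_year = 2020) {
  stopifnot(year >= base_year)
  total <- legacy_fleet_nox(year, legacy, limits, distances, schedule)
  base_comp <- rates[, c("segment_key", "fuel", "count")]
  for (cy in base_year:year) {
    sf <- surviving_fraction(schedule, year - cy)
    if (sf == 0) next
    cells <- compose_cohort(spec, cy, base_comp, sales, base_year)
    kg <- .cell_nox_rate(cells, rates, profiles)
    total <- total + sum(cells$count * sf * kg) / 1000
  }
  total
}

#' Project whole-fleet NOx over a range of years
#'
#' @inheritParams fleet_annual_nox
#' @param years calendar years to evaluate.
#' @return data.frame `year`, `legacy_t`, `new_t`, `total_t` (tonnes).
#' @export
project_nox <- function(spec, years, rates, profiles, schedule,
                        legacy = legacy_fleet(),
                        limits = euro_nox_limits(),
                        distances = distance_assumptions(),
                        sales = sales_trajectory(), base_year = 2020) {
  leg <- vapply(years, legacy_fleet_nox, numeric(1), legacy = legacy,
                limits = limits, distances = distances,
                schedule = schedule)
  tot <- vapply(years, function(y)
    fleet_annual_nox(spec, y, rates, profiles, schedule, legacy, limits,
                     distances, sales, base_year), numeric(1))
  data.frame(year = years, legacy_t = leg, new_t = tot - leg,
             total_t = tot)
}

#' Urban background NO2 reduction relative to business as usual
#'
#' Fleet NOx is assumed to map proportionally onto the passenger-car
#' contribution to urban background NO2, held at 2.59 micrograms per
#' cubic metre under business as usual. The reduction is clamped to
#' `[0, baseline]`.
#'
#' @param bau_nox business-as-usual fleet NOx (tonnes), must be positive.
#' @param scen_nox scenario fleet NOx (tonnes).
#' @param baseline_no2 baseline concentration, micrograms per cubic metre.
#' @return reduction in micrograms per cubic metre.
#' @export
no2_delta <- function(bau_nox, scen_nox, baseline_no2 = 2.59) {
  if (any(bau_nox <= 0))
    stop("bau_nox must be positive", call. = FALSE)
  pmin(pmax(baseline_no2 * (1 - scen_nox / bau_nox), 0), baseline_no2)
}

#' NO2 reduction series for a scenario
#'
#' @param bau,scen data.frames from [project_nox()] sharing the same
#'   years.
#' @inheritParams no2_delta
#' @return data.frame `year`, `delta` (micrograms per cubic metre).
#' @export
no2_delta_series <- function(bau, scen, baseline_no2 = 2.59) {
  stopifnot(identical(bau$year, scen$year))
  data.frame(year = bau$year,
             delta = no2_delta(bau$total_t, scen$total_t, baseline_no2))
}
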