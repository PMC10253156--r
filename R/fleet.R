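#' @keywords internal
"_PACKAGE"

## Controlled vocabularies --------------------------------------------------

#' EURO passenger-car market segments accepted on input
#' @export
EURO_SEGMENTS <- c("A", "B", "C", "D", "E", "F", "J", "M", "S")

#' Segment keys used throughout the pipeline (J split by kerb mass)
#' @export
SEGMENT_KEYS <- c("A", "B", "C", "D", "E", "F",
                  "small_suv", "medium_suv", "large_suv", "M", "S")

#' Fuel classes accepted on input
#' @export
FUEL_CLASSES <- c("petrol", "diesel", "petrol_hybrid", "diesel_hybrid",
                  "petrol_phev", "bev")

DIESEL_FAMILY <- c("diesel", "diesel_hybrid")
PETROL_FAMILY <- c("petrol", "petrol_hybrid", "petrol_phev")

## Distance assumptions -----------------------------------------------------

#' Annual distance driven by fuel class
#'
#' Mean annual distances: petrol-family cars 10,137 km and diesel-family cars
#' 15,125 km (National Travel Survey means for England), battery-electric
#' cars 15,180 km. Hybrids inherit the distance of their base fuel;
#' plug-in hybrids are treated as petrol.
#'
#' @param petrol,diesel,bev annual km for each fuel family.
#' @return an object of class `distance_assumptions`.
#' @export
distance_assumptions <- function(petrol = 10137, diesel = 15125, bev = 15180) {
  d <- c(petrol = petrol, diesel = diesel, bev = bev)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("annual distances must be strictly positive", call. = FALSE)
  structure(as.list(d), class = "distance_assumptions")
}

#' Annual distance for a fuel class
#'
#' @param fuel character vector of fuel classes.
#' @param distances a [distance_assumptions()] object.
#' @return numeric vector of km/year.
#' @export
fuel_distance <- function(fuel, distances = distance_assumptions()) {
  stopifnot(inherits(distances, "distance_assumptions"))
  bad <- setdiff(unique(fuel), FUEL_CLASSES)
  if (length(bad))
    stop("unknown fuel class: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- numeric(length(fuel))
  out[fuel %in% PETROL_FAMILY] <- distances$petrol
  out[fuel %in% DIESEL_FAMILY] <- distances$diesel
  out[fuel == "bev"] <- distances$bev
  out
}

## Segment classification ---------------------------------------------------

#' Classify a vehicle into a segment key
#'
#' Non-SUV EURO segments pass through unchanged. The J (SUV) segment is
#' sub-classified by kerb mass: small below 1500 kg, medium 1500-2000 kg
#' (both boundaries inclusive), large above 2000 kg.
#'
#' @param segment character vector of EURO segment labels (A-F, J, M, S).
#' @param kerb_mass numeric vector of kerb masses in kg.
#' @return character vector of segment keys (see [SEGMENT_KEYS]).
#' @examples
#' classify_segment("J", 2100)  # "large_suv"
#' classify_segment("B", 1200)  # "B"
#' @export
classify_segment <- function(segment, kerb_mass) {
  segment <- as.character(segment)
  bad <- setdiff(unique(segment), EURO_SEGMENTS)
  if (length(bad))
    stop("unknown EURO segment label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(kerb_mass)) || any(kerb_mass <= 0))
    stop("kerb_mass must be strictly positive", call. = FALSE)
  out <- segment
  j <- segment == "J"
  out[j & kerb_mass < 1500] <- "small_suv"
  out[j & kerb_mass >= 1500 & kerb_mass <= 2000] <- "medium_suv"
  out[j & kerb_mass > 2000] <- "large_suv"
  out
}

## Per-model annual emissions ----------------------------------------------

#' Annual CO2 emissions for one vehicle model
#'
#' `C x R x D / 1e6` tonnes: type-approval CO2 (g/km) times registrations
#' times annual distance, converted from grams to tonnes.
#'
#' @param co2_g_km CO2 emission rate, g/km.
#' @param registrations number of vehicles.
#' @param distance_km annual distance per vehicle, km.
#' @return tonnes CO2 per year.
#' @export
annual_model_co2 <- function(co2_g_km, registrations, distance_km) {
  .check_nonneg(co2_g_km, "co2_g_km")
  .check_nonneg(registrations, "registrations")
  .check_nonneg(distance_km, "distance_km")
  co2_g_km * registrations * distance_km / 1e6
}

#' Annual NOx emissions for one vehicle model
#'
#' `N x R x D / 1e9` tonnes: on-road NOx (mg/km) times registrations times
#' annual distance, converted from milligrams to tonnes.
#'
#' @param nox_mg_km NOx emission rate, mg/km.
#' @inheritParams annual_model_co2
#' @return tonnes NOx per year.
#' @export
annual_model_nox <- function(nox_mg_km, registrations, distance_km) {
  .check_nonneg(nox_mg_km, "nox_mg_km")
  .check_nonneg(registrations, "registrations")
  .check_nonneg(distance_km, "distance_km")
  nox_mg_km * registrations * distance_km / 1e9
}

.check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(name, " must be non-negative and finite", call. = FALSE)
  invisible(x)
}

## Vehicle model records ----------------------------------------------------

FLEET_COLUMNS <- c("model_id", "registrations", "segment", "fuel",
                   "kerb_mass", "wltp_test_mass", "engine_capacity",
                   "wheelbase", "co2_wltp", "nox_rde")

#' Validate a table of vehicle model records
#'
#' Checks the column set, types and the per-record invariants: non-negative
#' registrations and emissions, strictly positive masses, and zero CO2 and
#' NOx for battery-electric records. `nox_rde` may be `NA` (models with no
#' on-road NOx test); such records are retained for CO2 accounting and
#' excluded from NOx profiles.
#'
#' @param records data.frame with the columns listed in the fleet file
#'   format (see [read_fleet()]).
#' @return the validated data.frame, invisibly classed `vehicle_records`.
#' @export
validate_fleet <- function(records) {
  missing_cols <- setdiff(FLEET_COLUMNS, names(records))
  if (length(missing_cols))
    stop("fleet table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records)[FLEET_COLUMNS]

  fail <- function(rows, what) {
    stop("invalid fleet records (rows ", paste(rows, collapse = ", "),
         "): ", what, call. = FALSE)
  }
  chk <- function(bad, what) {
    if (any(bad)) fail(which(bad), what)
  }
  bad_seg <- !(records$segment %in% EURO_SEGMENTS)
  if (any(bad_seg))
    fail(which(bad_seg), paste0("unknown EURO segment label: ",
         paste(unique(records$segment[bad_seg]), collapse = ", ")))
  chk(!(records$fuel %in% FUEL_CLASSES), "unknown fuel class")
  num <- c("registrations", "kerb_mass", "wltp_test_mass",
           "engine_capacity", "wheelbase", "co2_wltp")
  for (col in num) {
    chk(!is.finite(records[[col]]), paste0(col, " must be numeric"))
  }
  chk(records$registrations < 0, "registrations must be >= 0")
  chk(records$kerb_mass <= 0 | records$wltp_test_mass <= 0,
      "masses must be > 0")
  chk(records$co2_wltp < 0, "co2_wltp must be >= 0")
  chk(records$engine_capacity < 0, "engine_capacity must be >= 0")
  chk(records$wheelbase <= 0, "wheelbase must be > 0")
  chk(!is.na(records$nox_rde) & records$nox_rde < 0,
      "nox_rde must be >= 0 when present")
  bev <- records$fuel == "bev"
  chk(bev & records$co2_wltp != 0, "BEV records must have co2_wltp = 0")
  chk(bev & !is.na(records$nox_rde) & records$nox_rde != 0,
      "BEV records must have nox_rde = 0")
  class(records) <- c("vehicle_records", "data.frame")
  invisible(records)
}

#' Read a fleet file
#'
#' Comma-separated, one row per vehicle model, header
#' `model_id,registrations,segment,fuel,kerb_mass,wltp_test_mass,
#' engine_capacity,wheelbase,co2_wltp,nox_rde`. Units: kg, cm3, mm, g/km,
#' mg/km. An empty `nox_rde` field means no on-road NOx test is available
#' for that model. Validation failures report the offending row numbers.
#'
#' @param path file path.
#' @return a validated `vehicle_records` data.frame.
#' @export
read_fleet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_fleet(df)
}

#' Write a fleet file
#'
#' @param records a `vehicle_records` data.frame (validated on the way out).
#' @param path file path.
#' @export
write_fleet <- function(records, path) {
  records <- validate_fleet(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## Segment profiles ---------------------------------------------------------

#' Per-segment annual emission profiles
#'
#' Aggregates per-model annual emissions into per-segment means: total
#' segment emissions divided by segment vehicle count. NOx means use only
#' the models with an on-road NOx value, divided by the registrations of
#' those models. The emission-share/registration-share ratios express how
#' far a segment's emission share exceeds its share of registrations
#' (fleet-weighted mean ratio is 1 by construction).
#'
#' @param records a `vehicle_records` data.frame.
#' @param distances a [distance_assumptions()] object.
#' @return a `segment_profiles` data.frame with columns `segment_key`,
#'   `n_vehicles`, `n_models`, `n_vehicles_nox` (registrations with NOx
#'   data), `mean_annual_co2` (tonnes/vehicle/year), `mean_annual_nox`
#'   (kg/vehicle/year), `co2_registration_ratio`, `nox_registration_ratio`.
#' @export
build_segment_profiles <- function(records,
                                   distances = distance_assumptions()) {
  records <- validate_fleet(records)
  if (nrow(records) == 0L)
    stop("no vehicle records supplied", call. = FALSE)
  key <- classify_segment(records$segment, records$kerb_mass)
  dist <- fuel_distance(records$fuel, distances)
  co2_t <- annual_model_co2(records$co2_wltp, records$registrations, dist)
  has_nox <- !is.na(records$nox_rde)
  nox_t <- rep(0, nrow(records))
  nox_t[has_nox] <- annual_model_nox(records$nox_rde[has_nox],
                                     records$registrations[has_nox],
                                     dist[has_nox])

  keys <- intersect(SEGMENT_KEYS, unique(key))
  empty <- setdiff(SEGMENT_KEYS, keys)
  if (length(empty))
    warning("segments with no records omitted from profiles: ",
            paste(empty, collapse = ", "), call. = FALSE)

  agg <- function(x, idx) vapply(keys, function(k)
    sum(x[idx & key == k]), numeric(1))
  all_idx <- rep(TRUE, nrow(records))
  n_veh <- agg(records$registrations, all_idx)
  n_mod <- vapply(keys, function(k) sum(key == k), numeric(1))
  n_veh_nox <- agg(records$registrations, has_nox)
  co2_seg <- agg(co2_t, all_idx)
  nox_seg <- agg(nox_t, has_nox)

  zero_nox <- n_veh_nox == 0
  if (any(zero_nox))
    warning("segments with no NOx-tested records (NOx mean set NA): ",
            paste(keys[zero_nox], collapse = ", "), call. = FALSE)

  tot_co2 <- sum(co2_seg); tot_reg <- sum(n_veh)
  tot_nox <- sum(nox_seg); tot_reg_nox <- sum(n_veh_nox)
  mean_nox <- ifelse(zero_nox, NA_real_, 1000 * nox_seg / n_veh_nox)
  nox_ratio <- if (tot_nox > 0)
    ifelse(zero_nox, NA_real_,
           (nox_seg / tot_nox) / (n_veh_nox / tot_reg_nox))
  else rep(NA_real_, length(keys))

  out <- data.frame(
    segment_key = keys,
    n_vehicles = n_veh,
    n_models = n_mod,
    n_vehicles_nox = n_veh_nox,
    mean_annual_co2 = co2_seg / n_veh,
    mean_annual_nox = mean_nox,
    co2_registration_ratio = if (tot_co2 > 0)
      (co2_seg / tot_co2) / (n_veh / tot_reg) else NA_real_,
    nox_registration_ratio = nox_ratio,
    row.names = NULL
  )
  class(out) <- c("segment_profiles", "data.frame")
  out
}

#' @export
print.segment_profiles <- function(x, digits = 3, ...) {
  cat("Per-segment annual emission profiles\n")
  cat(sprintf("  %d segments, %s vehicles (%s with NOx data)\n",
              nrow(x), format(sum(x$n_vehicles), big.mark = ","),
              format(sum(x$n_vehicles_nox), big.mark = ",")))
  df <- as.data.frame(x)
  df$mean_annual_co2 <- round(df$mean_annual_co2, digits)
  df$mean_annual_nox <- round(df$mean_annual_nox, digits)
  df$co2_registration_ratio <- round(df$co2_registration_ratio, digits)
  df$nox_registration_ratio <- round(df$nox_registration_ratio, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

## Cell-level emission rates (segment x fuel) -------------------------------

#' Per-vehicle annual emission rates by segment and fuel
#'
#' Registration-weighted mean annual CO2 (tonnes/vehicle) and NOx
#' (kg/vehicle) for every segment-fuel cell present in the fleet, used by
#' the scenario projections. Also records the fleet-wide petrol plug-in
#' hybrid means, which stand in for plug-in hybrid sales in segments that
#' had none in the base year.
#'
#' @inheritParams build_segment_profiles
#' @return an `emission_rates` data.frame with columns `segment_key`,
#'   `fuel`, `count`, `co2_t_per_vehicle`, `nox_kg_per_vehicle` plus
#'   attributes `phev_co2`, `phev_nox` (fleet-wide plug-in hybrid means)
#'   and `bev_share` (base-year BEV registration share).
#' @export
emission_rates <- function(records, distances = distance_assumptions()) {
  records <- validate_fleet(records)
  key <- classify_segment(records$segment, records$kerb_mass)
  dist <- fuel_distance(records$fuel, distances)
  co2_t <- annual_model_co2(records$co2_wltp, records$registrations, dist)
  has_nox <- !is.na(records$nox_rde)
  nox_kg <- ifelse(has_nox,
                   1000 * annual_model_nox(ifelse(has_nox, records$nox_rde, 0),
                                           records$registrations, dist), NA)

  cell <- interaction(key, records$fuel, drop = TRUE, sep = "\r")
  count <- tapply(records$registrations, cell, sum)
  co2_cell <- tapply(co2_t, cell, sum) / count
  nox_num <- tapply(ifelse(has_nox, nox_kg, 0), cell, sum)
  nox_den <- tapply(records$registrations * has_nox, cell, sum)
  nox_cell <- ifelse(nox_den > 0, nox_num / nox_den, NA_real_)

  parts <- strsplit(names(count), "\r", fixed = TRUE)
  out <- data.frame(
    segment_key = vapply(parts, `[`, "", 1L),
    fuel = vapply(parts, `[`, "", 2L),
    count = as.numeric(count),
    co2_t_per_vehicle = as.numeric(co2_cell),
    nox_kg_per_vehicle = as.numeric(nox_cell),
    row.names = NULL
  )
  out <- out[order(match(out$segment_key, SEGMENT_KEYS),
                   match(out$fuel, FUEL_CLASSES)), ]
  rownames(out) <- NULL

  phev <- records$fuel == "petrol_phev"
  phev_reg <- sum(records$registrations[phev])
  phev_co2 <- if (phev_reg > 0) sum(co2_t[phev]) / phev_reg else 0
  pn <- phev & has_nox
  phev_nox_reg <- sum(records$registrations[pn])
  phev_nox <- if (phev_nox_reg > 0)
    sum(1000 * annual_model_nox(records$nox_rde[pn],
                                records$registrations[pn],
                                dist[pn])) / phev_nox_reg
  else 0
  structure(out,
            class = c("emission_rates", "data.frame"),
            phev_co2 = phev_co2,
            phev_nox = phev_nox,
            bev_share = sum(records$registrations[records$fuel == "bev"]) /
              sum(records$registrations))
}
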