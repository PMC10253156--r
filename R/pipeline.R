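## One reproducible end-to-end run: synthetic (or file-based) inputs,
## segment profiles, regressions, survival calibration, scenario CO2 and
## NOx projections, NO2 deltas, life-table health impacts and valuation,
## written out as delimited tables plus a run manifest.

#' Default pipeline configuration
#'
#' All tunable quantities of a full run in one list. Fleet and population
#' are generated synthetically unless file paths are supplied.
#'
#' @param seed integer seed for the synthetic generators.
#' @param out_dir output directory (created if needed).
#' @param fleet_file,population_file optional input files replacing the
#'   synthetic generators.
#' @param scenarios character vector of preset scenario names to run.
#' @param horizons CO2 accounting horizons.
#' @param nox_years calendar years over which fleet NOx is projected (the
#'   last value of the NO2 reduction series is held constant afterwards
#'   for the life table).
#' @param end_year life-table follow-up end.
#' @param base_year policy start year.
#' @param grid a [grid_intensity_series()] object.
#' @param limits a [euro_nox_limits()] table.
#' @param legacy a [legacy_fleet()] data.frame.
#' @param distances a [distance_assumptions()] object.
#' @param milestones,median_age,max_age survival calibration inputs.
#' @param prices carbon prices, as [carbon_prices()].
#' @param volys,discount_rates,coefficients sensitivity grid axes.
#' @param baseline_no2 urban background NO2 under business as usual.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1L,
                               out_dir = file.path(tempdir(), "fleetair"),
                               fleet_file = NULL, population_file = NULL,
                               scenarios = SCENARIO_NAMES,
                               horizons = c(2035, 2050),
                               nox_years = 2020:2060,
                               end_year = 2126,
                               base_year = 2020,
                               grid = grid_intensity_series(),
                               limits = euro_nox_limits(),
                               legacy = legacy_fleet(),
                               distances = distance_assumptions(),
                               milestones = c("5" = 0.41, "10" = 0.77,
                                              "15" = 0.96),
                               median_age = 14, max_age = 25,
                               prices = carbon_prices(),
                               volys = c(20000, 60000),
                               discount_rates = c(0.015, 0.035),
                               coefficients = c(1.008, 1.023, 1.037),
                               baseline_no2 = 2.59) {
  bad <- setdiff(scenarios, SCENARIO_NAMES)
  if (length(bad))
    stop("unknown scenario name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (f in c(fleet_file, population_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file does not exist: ", f, call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields override the defaults of [default_run_config()];
#' structured fields accept the natural YAML forms (named maps for
#' milestone coverages, grid anchors and price vectors).
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("seed", "out_dir", "fleet_file", "population_file",
               "scenarios", "horizons", "nox_years", "end_year",
               "base_year", "median_age", "max_age", "volys",
               "discount_rates", "coefficients", "baseline_no2"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$milestones)) args$milestones <- unlist(y$milestones)
  if (!is.null(y$grid_anchors))
    args$grid <- grid_intensity_series(unlist(y$grid_anchors))
  do.call(default_run_config, args)
}

.write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full pipeline
#'
#' Generates (or reads) the fleet and population, builds the segment
#' profiles and emission rates, fits the CO2 and NOx regressions,
#' calibrates the stock-turnover schedule, projects cumulative CO2 and
#' whole-fleet NOx for every requested scenario, translates NOx to NO2
#' reductions, runs the life table for every non-baseline scenario, and
#' writes all results as delimited tables plus a `manifest.json`
#' recording the seed and a configuration hash. Identical configuration
#' and seed give identical numeric outputs.
#'
#' @param config a [default_run_config()] list.
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with every intermediate and final result
#'   plus the written file paths.
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  files <- character(0)

  say("stage: inputs")
  fleet <- stage("inputs", {
    if (is.null(config$fleet_file))
      generate_fleet(fleet_gen_config(seed = config$seed))
    else read_fleet(config$fleet_file)
  })
  pop <- stage("inputs", {
    if (is.null(config$population_file))
      generate_population(population_gen_config(seed = config$seed))
    else read_population(config$population_file)
  })
  files["fleet"] <- .write_table(fleet, config$out_dir, "fleet.csv")

  say("stage: profiles")
  profiles <- stage("profiles",
                    build_segment_profiles(fleet, config$distances))
  rates <- stage("profiles", emission_rates(fleet, config$distances))
  files["profiles"] <- .write_table(as.data.frame(profiles),
                                    config$out_dir, "segment_profiles.csv")

  say("stage: regression")
  reg <- stage("regression", list(
    co2 = fit_co2_model(fleet),
    nox_diesel = fit_nox_model(fleet, "diesel"),
    nox_petrol = fit_nox_model(fleet, "petrol")
  ))
  files["regression_co2"] <- file.path(config$out_dir, "regression_co2.csv")
  write_ols_report(reg$co2, files["regression_co2"])
  files["regression_nox_diesel"] <-
    file.path(config$out_dir, "regression_nox_diesel.csv")
  write_ols_report(reg$nox_diesel, files["regression_nox_diesel"])
  files["regression_nox_petrol"] <-
    file.path(config$out_dir, "regression_nox_petrol.csv")
  write_ols_report(reg$nox_petrol, files["regression_nox_petrol"])

  say("stage: stock turnover")
  schedule <- stage("stock turnover",
                    calibrate_survival(config$milestones,
                                       config$median_age, config$max_age))
  files["survival"] <- file.path(config$out_dir, "survival_schedule.csv")
  write_survival_schedule(schedule, files["survival"])

  specs <- scenario_presets()[config$scenarios]
  sales <- sales_trajectory(config$base_year, sum(fleet$registrations))

  say("stage: CO2 projection")
  co2 <- stage("CO2 projection", {
    out <- list()
    for (nm in names(specs))
      for (h in config$horizons)
        out[[paste(nm, h)]] <- project_co2(specs[[nm]], h, rates, schedule,
                                           config$grid, sales,
                                           config$base_year)
    out
  })
  co2_tab <- do.call(rbind, lapply(co2, function(p)
    data.frame(scenario = p$scenario, horizon = p$horizon,
               cumulative_mt = p$cumulative_mt, bev_mt = p$bev_mt)))
  if ("BAU" %in% co2_tab$scenario) {
    bau <- co2_tab[co2_tab$scenario == "BAU", ]
    co2_tab$pct_change_vs_bau <- round(percent_change(
      co2_tab$cumulative_mt,
      bau$cumulative_mt[match(co2_tab$horizon, bau$horizon)]))
    val <- do.call(rbind, lapply(seq_len(nrow(co2_tab)), function(i) {
      h <- as.character(co2_tab$horizon[i])
      saving <- bau$cumulative_mt[match(co2_tab$horizon[i], bau$horizon)] -
        co2_tab$cumulative_mt[i]
      p <- config$prices[[h]]
      data.frame(scenario = co2_tab$scenario[i], horizon = co2_tab$horizon[i],
                 saving_mt = saving,
                 value_low_bn = round(value_carbon(max(saving, 0), p[["low"]])),
                 value_central_bn = round(value_carbon(max(saving, 0),
                                                       p[["central"]])),
                 value_high_bn = round(value_carbon(max(saving, 0),
                                                    p[["high"]])))
    }))
    files["carbon_value"] <- .write_table(val, config$out_dir,
                                          "carbon_value.csv")
  } else val <- NULL
  files["cumulative_co2"] <- .write_table(co2_tab, config$out_dir,
                                          "cumulative_co2.csv")
  ann <- do.call(rbind, lapply(co2[grep(max(config$horizons),
                                        names(co2))], function(p)
    data.frame(scenario = p$scenario, year = as.integer(names(p$annual_mt)),
               annual_mt = p$annual_mt, annual_new_mt = p$annual_new_mt)))
  files["annual_co2"] <- .write_table(ann, config$out_dir, "annual_co2.csv")

  say("stage: NOx projection")
  nox <- stage("NOx projection", {
    lapply(specs, function(sp)
      project_nox(sp, config$nox_years, rates, profiles, schedule,
                  config$legacy, config$limits, config$distances, sales,
                  config$base_year))
  })
  nox_tab <- do.call(rbind, lapply(names(nox), function(nm)
    cbind(scenario = nm, nox[[nm]])))
  files["fleet_nox"] <- .write_table(nox_tab, config$out_dir,
                                     "fleet_nox.csv")

  deltas <- NULL
  hia_tab <- NULL
  sens <- NULL
  if ("BAU" %in% names(nox) && length(specs) > 1) {
    say("stage: NO2 deltas")
    deltas <- stage("NO2 deltas", {
      lapply(nox[setdiff(names(nox), "BAU")], function(sc)
        no2_delta_series(nox$BAU, sc, config$baseline_no2))
    })
    delta_tab <- do.call(rbind, lapply(names(deltas), function(nm)
      cbind(scenario = nm, deltas[[nm]])))
    files["no2_delta"] <- .write_table(delta_tab, config$out_dir,
                                       "no2_delta.csv")

    say("stage: health impact")
    hia <- stage("health impact", {
      lapply(deltas, function(d)
        life_years_gained(pop,
                          stats::setNames(d$delta, d$year),
                          end_year = config$end_year))
    })
    central <- valuation_params()
    hia_tab <- do.call(rbind, lapply(names(hia), function(nm)
      data.frame(scenario = nm, life_years = hia[[nm]]$total,
                 value_gbp_m = value_life_years(hia[[nm]]$by_year, central,
                                                config$base_year) / 1e6)))
    if ("Electrified" %in% hia_tab$scenario) {
      el <- hia_tab[hia_tab$scenario == "Electrified", ]
      hia_tab$pct_ly_vs_electrified <-
        round(percent_change(hia_tab$life_years, el$life_years), 1)
      hia_tab$pct_value_vs_electrified <-
        round(percent_change(hia_tab$value_gbp_m, el$value_gbp_m), 1)
    }
    files["life_years"] <- .write_table(hia_tab, config$out_dir,
                                        "life_years.csv")

    if ("ElectrifiedSmallSUV" %in% names(deltas)) {
      say("stage: sensitivity")
      d <- deltas$ElectrifiedSmallSUV
      sens <- stage("sensitivity",
                    sensitivity_grid(pop, stats::setNames(d$delta, d$year),
                                     volys = config$volys,
                                     rates = config$discount_rates,
                                     coefficients = config$coefficients,
                                     end_year = config$end_year,
                                     base_year = config$base_year))
      sens$value_gbp_m <- sens$value_gbp / 1e6
      files["sensitivity"] <- .write_table(sens, config$out_dir,
                                           "sensitivity.csv")
    }
  }

  manifest <- list(
    package = "fleetair",
    version = as.character(utils::packageVersion("fleetair")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = .config_hash(config),
    scenarios = config$scenarios,
    n_models = nrow(fleet),
    total_registrations = sum(fleet$registrations)
  )
  files["manifest"] <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(config = config, fleet = fleet, population = pop,
                 profiles = profiles, rates = rates, regressions = reg,
                 schedule = schedule, co2 = co2, co2_table = co2_tab,
                 carbon_value = val, nox = nox, deltas = deltas,
                 health = hia_tab, sensitivity = sens, files = files))
}

# stable hash of the configuration: serialised to a canonical text form
.config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12,
                                                vec.len = 1e6)),
               collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
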