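## Scenario engine: composition of new registrations by segment and fuel
## for each calendar year under the five policy scenarios.
##
## Substitution scenarios move whole segments (1:1, count preserving) and
## the moved vehicles adopt the target segment's emission profile and fuel
## mix. Electrified scenarios overlay a fleet-wide BEV sales share applied
## uniformly within every segment; residual non-BEV sales keep the
## segment's base-year petrol/diesel mix until 2030 and are petrol plug-in
## hybrids from 2030 until the 2035 full-electrification year. Where both
## apply, substitution runs first, then electrification.

SCENARIO_NAMES <- c("BAU", "SmallSUV", "NoSUV", "Electrified",
                    "ElectrifiedSmallSUV")

#' Define a fleet policy scenario
#'
#' @param name scenario label.
#' @param substitution named character vector mapping source segment keys
#'   to target segment keys (1:1 count-preserving replacement), or `NULL`.
#' @param bev_anchors named numeric vector of BEV sales-share anchors by
#'   year (e.g. `c("2025" = .25, "2030" = .70, "2035" = 1)`), or `NULL`
#'   for a constant base-year share. Shares are linearly interpolated from
#'   the base-year share and saturate at 1 after the last anchor.
#' @param phev_from,phev_until calendar years between which residual
#'   non-BEV sales are petrol plug-in hybrids (electrified scenarios).
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name, substitution = NULL, bev_anchors = NULL,
                          phev_from = 2030, phev_until = 2035) {
  if (!is.null(substitution)) {
    bad <- setdiff(c(names(substitution), substitution), SEGMENT_KEYS)
    if (length(bad))
      stop("unknown segment keys in substitution map: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(bev_anchors)) {
    yr <- as.integer(names(bev_anchors))
    if (any(is.na(yr)) || is.unsorted(yr, strictly = TRUE))
      stop("bev_anchors must be named by strictly increasing years",
           call. = FALSE)
    if (any(bev_anchors < 0 | bev_anchors > 1) ||
        is.unsorted(bev_anchors))
      stop("bev_anchors must be non-decreasing shares in [0, 1]",
           call. = FALSE)
  }
  structure(list(name = name, substitution = substitution,
                 bev_anchors = bev_anchors,
                 phev_from = phev_from, phev_until = phev_until),
            class = "scenario_spec")
}

#' The five canonical scenarios
#'
#' Business as usual (constant base-year composition); Small SUV (medium
#' and large SUV sales replaced by small SUVs from 2020, 1:1); No SUV
#' (small/medium/large SUVs replaced by segment B/C/D cars, 1:1);
#' Electrified (BEV sales share 25 percent in 2025, 70 percent in 2030,
#' 100 percent from 2035, residual sales petrol plug-in hybrid over
#' 2030-2035); Electrified and Small SUV (both, substitution applied
#' first).
#'
#' @return named list of `scenario_spec` objects.
#' @export
scenario_presets <- function() {
  anchors <- c("2025" = 0.25, "2030" = 0.70, "2035" = 1.0)
  small <- c(medium_suv = "small_suv", large_suv = "small_suv")
  nosuv <- c(small_suv = "B", medium_suv = "C", large_suv = "D")
  list(
    BAU = scenario_spec("BAU"),
    SmallSUV = scenario_spec("SmallSUV", substitution = small),
    NoSUV = scenario_spec("NoSUV", substitution = nosuv),
    Electrified = scenario_spec("Electrified", bev_anchors = anchors),
    ElectrifiedSmallSUV = scenario_spec("ElectrifiedSmallSUV",
                                        substitution = small,
                                        bev_anchors = anchors)
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (!is.null(x$substitution))
    cat("  substitution:",
        paste(names(x$substitution), "->", x$substitution,
              collapse = ", "), "\n")
  if (!is.null(x$bev_anchors))
    cat("  BEV share anchors:",
        paste(names(x$bev_anchors), "=", x$bev_anchors, collapse = ", "),
        "\n")
  invisible(x)
}

#' BEV share of new sales in a calendar year
#'
#' Scenarios without electrification anchors keep the base-year share
#' constant. Electrified scenarios interpolate linearly from the base-year
#' share through the anchors and saturate at 1 after the last anchor.
#'
#' @param spec a `scenario_spec`.
#' @param year calendar year (>= base year).
#' @param base_share BEV share of base-year registrations.
#' @param base_year first modelled year.
#' @return share in `[0, 1]`.
#' @export
bev_share <- function(spec, year, base_share = 0.0466, base_year = 2020) {
  stopifnot(inherits(spec, "scenario_spec"), all(year >= base_year))
  if (is.null(spec$bev_anchors)) return(rep(base_share, length(year)))
  xs <- c(base_year, as.integer(names(spec$bev_anchors)))
  ys <- c(base_share, as.numeric(spec$bev_anchors))
  stats::approx(xs, ys, xout = pmin(year, max(xs)), rule = 2)$y
}

#' New-sales trajectory
#'
#' The base year keeps its observed (pandemic-suppressed) registration
#' count; sales return to 2.5 million units from the following year and
#' stay constant.
#'
#' @param base_year first modelled year.
#' @param base_count registrations in the base year.
#' @param steady_count annual registrations thereafter.
#' @return a function of calendar year returning the sales count.
#' @export
sales_trajectory <- function(base_year = 2020, base_count = 1560452,
                             steady_count = 2.5e6) {
  stopifnot(base_count > 0, steady_count > 0)
  function(year) {
    stopifnot(all(year >= base_year))
    ifelse(year == base_year, base_count, steady_count)
  }
}

#' Compose a year's sales cohort under a scenario
#'
#' Distributes the year's sales over segment x fuel cells: base-year
#' composition shares, then segment substitution (moved vehicles take the
#' target segment's base-year fuel mix), then the electrification overlay.
#' Total count is preserved exactly at every step.
#'
#' @param spec a `scenario_spec`.
#' @param year calendar year.
#' @param base_composition data.frame `segment_key`, `fuel`, `count`
#'   describing the base-year fleet (e.g. the `count` columns of
#'   [emission_rates()]).
#' @param sales a [sales_trajectory()] function (or a single count).
#' @param base_year first modelled year.
#' @return data.frame `segment_key`, `fuel`, `count` with attributes
#'   `year` and `scenario`.
#' @export
compose_cohort <- function(spec, year, base_composition,
                           sales = sales_trajectory(), base_year = 2020) {
  stopifnot(inherits(spec, "scenario_spec"), length(year) == 1,
            year >= base_year)
  comp <- as.data.frame(base_composition)[c("segment_key", "fuel", "count")]
  if (any(comp$count < 0)) stop("negative base counts", call. = FALSE)
  total <- if (is.function(sales)) sales(year) else sales

  comp$count <- comp$count / sum(comp$count) * total

  # 1:1 segment substitution; moved count adopts the target's fuel mix
  if (!is.null(spec$substitution)) {
    for (src in names(spec$substitution)) {
      tgt <- spec$substitution[[src]]
      tgt_rows <- comp$segment_key == tgt
      if (!any(tgt_rows))
        stop("substitution target segment absent from base composition: ",
             tgt, call. = FALSE)
      src_rows <- comp$segment_key == src
      moved <- sum(comp$count[src_rows])
      if (moved > 0) {
        mix <- comp$count[tgt_rows] / sum(comp$count[tgt_rows])
        comp$count[tgt_rows] <- comp$count[tgt_rows] + moved * mix
        comp$count[src_rows] <- 0
      }
    }
  }

  # electrification overlay, uniform across segments
  if (!is.null(spec$bev_anchors) && year > base_year) {
    share <- bev_share(spec, year, base_share = .base_bev_share(comp),
                       base_year = base_year)
    segs <- unique(comp$segment_key)
    new_rows <- lapply(segs, function(sg) {
      rows <- comp[comp$segment_key == sg, , drop = FALSE]
      seg_total <- sum(rows$count)
      if (seg_total == 0) return(rows)
      resid <- seg_total * (1 - share)
      if (year >= spec$phev_from) {
        out <- data.frame(segment_key = sg,
                          fuel = c("bev", "petrol_phev"),
                          count = c(seg_total * share, resid))
      } else {
        ice <- rows[rows$fuel != "bev", , drop = FALSE]
        if (nrow(ice) == 0 || sum(ice$count) == 0) {
          out <- data.frame(segment_key = sg, fuel = "bev",
                            count = seg_total)
        } else {
          mix <- ice$count / sum(ice$count)
          out <- rbind(
            data.frame(segment_key = sg, fuel = "bev",
                       count = seg_total * share),
            data.frame(segment_key = sg, fuel = ice$fuel,
                       count = resid * mix))
        }
      }
      out[out$count > 0 | out$fuel == "bev", , drop = FALSE]
    })
    comp <- do.call(rbind, new_rows)
    comp <- stats::aggregate(count ~ segment_key + fuel, comp, sum)
  }

  comp <- comp[comp$count > 0, , drop = FALSE]
  comp <- comp[order(match(comp$segment_key, SEGMENT_KEYS),
                     match(comp$fuel, FUEL_CLASSES)), ]
  rownames(comp) <- NULL
  structure(comp, year = year, scenario = spec$name)
}

.base_bev_share <- function(comp) {
  sum(comp$count[comp$fuel == "bev"]) / sum(comp$count)
}
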