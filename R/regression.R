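## Ordinary least squares with classical inference for the emission models.
##
## Fitting is delegated to stats::lm; this module owns the model
## definitions (which records enter, how fuels are coded), the rank checks
## and the summary container mirroring the published regression tables.

.ols_summary <- function(fit, n, response) {
  sm <- summary(fit)
  est <- stats::coef(sm)
  ci <- stats::confint(fit, level = 0.95)
  out <- list(
    coefficients = data.frame(
      term = rownames(est),
      estimate = est[, "Estimate"],
      ci_lower = ci[, 1],
      ci_upper = ci[, 2],
      p_value = est[, "Pr(>|t|)"],
      row.names = NULL
    ),
    r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic["value"]),
    n_obs = n,
    response = response
  )
  class(out) <- "ols_summary"
  out
}

# rank check that names offending columns instead of silently dropping them
.check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear or degenerate ",
         "columns: ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the CO2 emission regression
#'
#' Regresses WLTP CO2 (g/km) on WLTP test mass, engine capacity, wheelbase
#' and a diesel indicator, with intercept, over all internal-combustion
#' records (BEVs excluded; hybrids are coded by their base fuel and
#' plug-in hybrids as petrol). Classical homoskedastic standard errors and
#' t-based 95 percent confidence intervals.
#'
#' @param records a `vehicle_records` data.frame.
#' @return an `ols_summary` with per-term estimates, confidence bounds and
#'   p-values, plus R-squared, F statistic and the number of observations.
#' @export
fit_co2_model <- function(records) {
  records <- validate_fleet(records)
  ice <- records[records$fuel != "bev", , drop = FALSE]
  if (nrow(ice) < 10)
    stop("need at least 10 internal-combustion records, got ", nrow(ice),
         call. = FALSE)
  df <- data.frame(
    co2 = ice$co2_wltp,
    wltp_test_mass = ice$wltp_test_mass,
    engine_capacity = ice$engine_capacity,
    wheelbase = ice$wheelbase,
    diesel = as.numeric(ice$fuel %in% DIESEL_FAMILY)
  )
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, -1]))
  .check_full_rank(X)
  fit <- stats::lm(co2 ~ wltp_test_mass + engine_capacity + wheelbase +
                     diesel, data = df)
  .ols_summary(fit, nrow(df), "co2_wltp (g/km)")
}

#' Fit the NOx emission regression for one fuel family
#'
#' Regresses on-road NOx (mg/km) on WLTP test mass and engine capacity,
#' with intercept, separately for the diesel family (diesel, diesel
#' hybrid) and the petrol family (petrol, petrol hybrid, petrol plug-in
#' hybrid). Only records with an observed NOx value are used.
#'
#' @param records a `vehicle_records` data.frame.
#' @param fuel `"diesel"` or `"petrol"` (fuel family).
#' @return an `ols_summary`.
#' @export
fit_nox_model <- function(records, fuel = c("diesel", "petrol")) {
  fuel <- match.arg(fuel)
  records <- validate_fleet(records)
  fam <- if (fuel == "diesel") DIESEL_FAMILY else PETROL_FAMILY
  sub <- records[records$fuel %in% fam & !is.na(records$nox_rde), ,
                 drop = FALSE]
  if (nrow(sub) < 10)
    stop("need at least 10 ", fuel, "-family records with NOx data, got ",
         nrow(sub), call. = FALSE)
  df <- data.frame(
    nox = sub$nox_rde,
    wltp_test_mass = sub$wltp_test_mass,
    engine_capacity = sub$engine_capacity
  )
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, -1]))
  .check_full_rank(X)
  fit <- stats::lm(nox ~ wltp_test_mass + engine_capacity, data = df)
  .ols_summary(fit, nrow(df), sprintf("nox_rde (mg/km), %s family", fuel))
}

#' @export
print.ols_summary <- function(x, digits = 4, ...) {
  cat("OLS fit:", x$response, "\n")
  cat(sprintf("  n = %d, R-squared = %.4f, F = %.1f\n",
              x$n_obs, x$r_squared, x$f_statistic))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, digits)
  tab$ci_lower <- signif(tab$ci_lower, digits)
  tab$ci_upper <- signif(tab$ci_upper, digits)
  tab$p_value <- format.pval(tab$p_value, digits = 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a regression summary as a delimited table
#'
#' One row per term (estimate, 95 percent CI bounds, p-value) followed by
#' the fit statistics, mirroring the shape of the published regression
#' tables.
#'
#' @param x an `ols_summary`.
#' @param path output file path.
#' @export
write_ols_report <- function(x, path) {
  stopifnot(inherits(x, "ols_summary"))
  tab <- x$coefficients
  tab$r_squared <- x$r_squared
  tab$f_statistic <- x$f_statistic
  tab$n_obs <- x$n_obs
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
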