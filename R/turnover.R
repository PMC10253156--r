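## Cohort stock-turnover model: the fraction of a sales cohort still in
## service at each vehicle age, calibrated so that under constant annual
## sales the post-policy share of the on-road fleet passes through the
## stated coverage milestones, with a median vehicle lifespan of 14 years.

#' Construct a vehicle survival schedule
#'
#' @param fractions numeric vector of surviving fractions at integer ages
#'   `0:(length(fractions) - 1)`. Must start at 1, be non-increasing, and
#'   end at 0.
#' @return a `survival_schedule` object.
#' @export
survival_schedule <- function(fractions) {
  s <- as.numeric(fractions)
  if (length(s) < 2 || any(!is.finite(s)))
    stop("fractions must be a numeric vector of length >= 2", call. = FALSE)
  if (abs(s[1] - 1) > 1e-12)
    stop("surviving fraction at age 0 must be 1", call. = FALSE)
  if (any(diff(s) > 1e-12))
    stop("surviving fractions must be non-increasing in age", call. = FALSE)
  if (abs(s[length(s)]) > 1e-12)
    stop("surviving fraction at the maximum age must be 0", call. = FALSE)
  structure(list(fractions = s, max_age = length(s) - 1L),
            class = "survival_schedule")
}

#' Surviving fraction at integer vehicle ages
#'
#' @param schedule a `survival_schedule`.
#' @param age integer vehicle ages (0 = year of registration). Ages past
#'   the schedule's maximum return 0.
#' @return numeric vector of fractions.
#' @export
surviving_fraction <- function(schedule, age) {
  stopifnot(inherits(schedule, "survival_schedule"))
  if (any(age < 0)) stop("vehicle age must be >= 0", call. = FALSE)
  out <- rep(0, length(age))
  inside <- age <= schedule$max_age
  out[inside] <- schedule$fractions[age[inside] + 1L]
  out
}

#' Steady-state fleet coverage of a post-policy sales stream
#'
#' Under constant annual sales, the fraction of the total on-road fleet
#' that consists of vehicles sold in the `age + 1` years since a policy
#' started: cumulative surviving stock of cohorts aged 0..age divided by
#' the total steady-state stock.
#'
#' @param schedule a `survival_schedule`.
#' @param age integer years since policy start.
#' @return coverage fraction(s) in `[0, 1]`.
#' @export
fleet_coverage <- function(schedule, age) {
  stopifnot(inherits(schedule, "survival_schedule"))
  s <- schedule$fractions
  cum <- cumsum(s)
  idx <- pmin(age, schedule$max_age) + 1L
  cum[idx] / sum(s)
}

#' Calibrate the survival schedule to fleet-coverage milestones
#'
#' Builds the piecewise-constant-within-span schedule implied by linear
#' interpolation of cumulative fleet coverage between the milestone ages,
#' anchored by a surviving fraction of exactly 0.5 at the median lifespan
#' age and 0 at `max_age`. The total steady-state stock per unit of annual
#' sales is fixed by the median constraint; adjacent spans whose implied
#' fractions would increase with age are pooled (averaged) to restore
#' monotonicity, which preserves the coverage values at the milestone ages
#' bounding the pooled region. With the default milestones the age-5
#' coverage cannot be met exactly by any non-increasing schedule that
#' starts at 1 (the implied age-wise retention would have to rise); it is
#' met approximately by pooling while the age-10 and age-15 milestones
#' hold exactly. Achieved coverages are stored in the `coverage` attribute
#' and shown by `print()`.
#'
#' @param milestones named numeric vector of coverage fractions at integer
#'   policy ages, e.g. `c("5" = 0.41, "10" = 0.77, "15" = 0.96)`. Must be
#'   strictly increasing in age and lie in (0, 1).
#' @param median_age vehicle age at which the surviving fraction is 0.5.
#'   Must fall inside the last milestone span.
#' @param max_age age by which the whole cohort has left service.
#' @return a `survival_schedule` with attributes `coverage` (achieved) and
#'   `target_coverage` (requested).
#' @export
calibrate_survival <- function(milestones = c("5" = 0.41, "10" = 0.77,
                                              "15" = 0.96),
                               median_age = 14, max_age = 25) {
  ages <- as.integer(names(milestones))
  cov <- as.numeric(milestones)
  if (length(ages) < 2 || any(is.na(ages)))
    stop("milestones must be named by integer ages", call. = FALSE)
  o <- order(ages); ages <- ages[o]; cov <- cov[o]
  if (any(diff(cov) <= 0) || any(cov <= 0) || any(cov >= 1))
    stop("milestone coverages must be strictly increasing and in (0, 1)",
         call. = FALSE)
  k <- length(ages)
  if (!(median_age > ages[k - 1] && median_age <= ages[k]))
    stop("median_age must lie inside the last milestone span (",
         ages[k - 1], ", ", ages[k], "]", call. = FALSE)
  if (max_age <= ages[k])
    stop("max_age must exceed the last milestone age", call. = FALSE)

  # Flat retention within the last milestone span pins the stock scale:
  # S = 0.5 across that span, so total stock W satisfies
  # (cov_k - cov_{k-1}) * W = 0.5 * span length.
  span_len <- diff(c(0L, ages))
  W <- 0.5 * span_len[k] / (cov[k] - cov[k - 1])

  # Implied flat retention per span (ages (a_{i-1}, a_i]); the first span
  # excludes age 0, which is fixed at S(0) = 1.
  seg_sum <- diff(c(0, cov)) * W
  seg_sum[1] <- seg_sum[1] - 1          # remove the age-0 vehicle
  seg_len <- span_len
  seg_len[1] <- seg_len[1] - 0L         # ages 1..a_1 -> a_1 values
  v <- seg_sum / seg_len

  # pool adjacent spans while retention increases with age
  repeat {
    bad <- which(diff(v) > 1e-12)
    if (!length(bad)) break
    i <- bad[1]
    seg_sum[i] <- seg_sum[i] + seg_sum[i + 1]
    seg_len[i] <- seg_len[i] + seg_len[i + 1]
    seg_sum <- seg_sum[-(i + 1)]; seg_len <- seg_len[-(i + 1)]
    v <- seg_sum / seg_len
  }
  if (v[1] > 1 + 1e-9)
    stop("infeasible milestones: implied retention exceeds 1 ",
         "(pooled span fractions: ", paste(signif(v, 4), collapse = ", "),
         ")", call. = FALSE)
  if (any(v < 0))
    stop("infeasible milestones: implied retention below 0", call. = FALSE)

  s <- c(1, rep(v, seg_len))            # ages 0..ages[k]

  # tail: linear decline from the last milestone age to 0 at max_age,
  # holding total stock at W
  n_tail <- max_age - ages[k]
  if (n_tail < 2)
    stop("max_age must be at least 2 years past the last milestone age",
         call. = FALSE)
  tail_sum <- (1 - cov[k]) * W
  wts <- (n_tail - seq_len(n_tail)) / (n_tail - 1)   # 1-step linear ramp to 0
  s0 <- tail_sum / sum(wts)
  tail_s <- s0 * wts
  if (tail_s[1] > s[length(s)] + 1e-9)
    stop("infeasible milestones: tail retention would exceed the last ",
         "span's (", signif(tail_s[1], 4), " > ",
         signif(s[length(s)], 4), ")", call. = FALSE)
  s <- c(s, tail_s)

  sched <- survival_schedule(s)
  ach <- fleet_coverage(sched, ages)
  attr(sched, "coverage") <- stats::setNames(ach, ages)
  attr(sched, "target_coverage") <- stats::setNames(cov, ages)
  sched
}

#' Vehicles of a sales cohort still in service in a calendar year
#'
#' A vehicle registered in `cohort_year` is age 0 and fully in service
#' during that year.
#'
#' @param cohort_size vehicles sold in the cohort year.
#' @param cohort_year year of first registration.
#' @param calendar_year year of interest (must not precede `cohort_year`).
#' @param schedule a `survival_schedule`.
#' @return surviving vehicle count.
#' @export
surviving_count <- function(cohort_size, cohort_year, calendar_year,
                            schedule) {
  age <- calendar_year - cohort_year
  if (any(age < 0))
    stop("calendar_year must not precede cohort_year", call. = FALSE)
  cohort_size * surviving_fraction(schedule, age)
}

#' Expected vehicle lifespan under a schedule
#'
#' Sum of the surviving fractions over all ages: the mean number of years
#' a vehicle stays in service (counting the registration year).
#'
#' @param schedule a `survival_schedule`.
#' @return expected service years.
#' @export
expected_lifespan <- function(schedule) {
  stopifnot(inherits(schedule, "survival_schedule"))
  sum(schedule$fractions)
}

#' @export
print.survival_schedule <- function(x, ...) {
  cat("Vehicle survival schedule (ages 0-", x$max_age, ")\n", sep = "")
  cat(sprintf("  expected lifespan %.2f years; S(14) = %.3f\n",
              expected_lifespan(x),
              surviving_fraction(x, min(14, x$max_age))))
  ach <- attr(x, "coverage")
  if (!is.null(ach)) {
    tgt <- attr(x, "target_coverage")
    cat("  fleet coverage at milestone ages (achieved / target):\n")
    for (i in seq_along(ach))
      cat(sprintf("    age %2s: %.3f / %.3f\n", names(ach)[i], ach[i],
                  tgt[i]))
  }
  invisible(x)
}

#' Read/write a survival schedule as a two-column delimited file
#'
#' Columns `age,surviving_fraction`, one row per integer age, so
#' alternative curves can be swapped in.
#'
#' @param schedule a `survival_schedule`.
#' @param path file path.
#' @return the schedule (read) or the path (write), invisibly.
#' @export
write_survival_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "survival_schedule"))
  utils::write.csv(data.frame(age = 0:schedule$max_age,
                              surviving_fraction = schedule$fractions),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_schedule
#' @export
read_survival_schedule <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "surviving_fraction") %in% names(df)))
    stop("schedule file needs columns age, surviving_fraction",
         call. = FALSE)
  df <- df[order(df$age), ]
  if (!identical(as.integer(df$age), seq_len(nrow(df)) - 1L))
    stop("schedule ages must be consecutive integers from 0", call. = FALSE)
  survival_schedule(df$surviving_fraction)
}
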