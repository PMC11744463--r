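# Discounted QALYs (trapezoidal area under the utility curve) and
# resource-use costing, per participant. Price year: GBP 2019-2020.

UNIT_COST_ITEMS <- c("surgery_episode", "theatre_minute", "bed_day",
                     "readmission_episode", "ae_attendance",
                     "primary_care_visit")

#' Unit-cost table
#'
#' A named non-negative numeric vector mapping resource items to GBP
#' unit costs (2019-2020 price year). Required items:
#' `surgery_episode`, `theatre_minute`, `bed_day`,
#' `readmission_episode`, `ae_attendance`, `primary_care_visit`.
#'
#' @param ... named item = cost pairs, or a single named vector/list.
#' @return A `unit_cost_table` (named numeric vector).
#' @export
unit_cost_table <- function(...) {
  x <- c(...)
  if (is.list(x)) x <- unlist(x)
  x <- structure(as.numeric(x), names = names(c(...)),
                 class = "unit_cost_table")
  validate_unit_costs(x)
  x
}

#' @noRd
validate_unit_costs <- function(costs) {
  missing <- setdiff(UNIT_COST_ITEMS, names(costs))
  if (length(missing)) {
    stop("unit-cost table lacks required item(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(unclass(costs)[UNIT_COST_ITEMS])) ||
      any(unclass(costs)[UNIT_COST_ITEMS] < 0)) {
    stop("unit costs must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a unit-cost table from CSV
#'
#' Expects columns `item`, `unit_cost_gbp` (a `unit` column, if
#' present, is ignored). `ref` may be a file path or the name of a
#' bundled fixture under `inst/extdata` (without extension). The
#' bundled `unit_costs_synthetic` table carries illustrative values,
#' not NHS reference costs.
#'
#' @param ref path or fixture name.
#' @return A `unit_cost_table`.
#' @export
load_unit_costs <- function(ref = "unit_costs_synthetic") {
  path <- if (file.exists(ref)) ref else
    system.file("extdata", paste0(ref, ".csv"), package = "cholecea")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unit-cost table not found: ", ref, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- structure(as.numeric(df$unit_cost_gbp), names = df$item,
                 class = "unit_cost_table")
  validate_unit_costs(x)
  x
}

#' Annual discount factor with an undiscounted first year
#'
#' Year one is not discounted; year `y > 1` is discounted by
#' \eqn{(1+r)^{-(y-1)}}.
#'
#' @param year_index 1-based year of accrual.
#' @param rate annual discount rate (proportion, >= 0).
#' @return Discount factor in (0, 1]. Vectorised over `year_index`.
#' @examples
#' annual_discount_factor(1, 0.035)  # 1
#' annual_discount_factor(2, 0.035)  # 1/1.035
#' @export
annual_discount_factor <- function(year_index, rate) {
  if (any(year_index < 1)) stop("year_index must be >= 1", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  (1 + rate)^(-(pmax(year_index, 1) - 1))
}

#' Discounted QALYs by trapezoidal area under the utility curve
#'
#' Integrates the utility trajectory over time (months converted to
#' years) with the trapezium rule; each trapezoid is discounted by the
#' factor of the year containing its midpoint (year one undiscounted).
#'
#' @param visit_months strictly increasing measurement times in months.
#' @param utilities utility values at those times; no missing values
#'   (impute upstream).
#' @param rate annual discount rate.
#' @return A list of class `qaly_profile`: `undiscounted`,
#'   `discounted`, and `per_interval` (data frame of interval
#'   contributions).
#' @examples
#' auc_qaly(c(0, 12, 24), c(1, 1, 1), rate = 0.035)$discounted
#' @export
auc_qaly <- function(visit_months, utilities, rate = 0.035) {
  if (length(visit_months) != length(utilities)) {
    stop("visit_months and utilities must have equal length", call. = FALSE)
  }
  if (length(visit_months) < 2 || any(diff(visit_months) <= 0)) {
    stop("visit_months must be strictly increasing (length >= 2)",
         call. = FALSE)
  }
  if (anyNA(utilities)) {
    stop("utilities contain missing values; impute before computing QALYs",
         call. = FALSE)
  }
  k <- length(visit_months)
  width_yr <- diff(visit_months) / 12
  area <- width_yr * (utilities[-k] + utilities[-1]) / 2
  mid <- (visit_months[-k] + visit_months[-1]) / 2
  fac <- annual_discount_factor(year_of_month(mid), rate)
  structure(list(
    undiscounted = sum(area),
    discounted = sum(area * fac),
    per_interval = data.frame(from = visit_months[-k], to = visit_months[-1],
                              area = area, factor = fac,
                              discounted = area * fac)
  ), class = "qaly_profile")
}

#' Per-participant discounted QALYs for a cohort (vectorised)
#'
#' @param data a `participant_data` data frame with complete utility
#'   columns.
#' @param rate annual discount rate.
#' @return Numeric vector of discounted QALYs, one per row of `data`.
#' @export
cohort_qalys <- function(data, rate = 0.035) {
  ucols <- grep("^util_", names(data), value = TRUE)
  months <- as.numeric(sub("^util_", "", ucols))
  o <- order(months)
  months <- months[o]
  um <- as.matrix(data[, ucols[o], drop = FALSE])
  if (anyNA(um)) {
    stop("utilities contain missing values; impute before computing QALYs",
         call. = FALSE)
  }
  k <- length(months)
  width_yr <- diff(months) / 12
  mid <- (months[-k] + months[-1]) / 2
  fac <- annual_discount_factor(year_of_month(mid), rate)
  w <- width_yr * fac / 2
  as.numeric(um[, -k, drop = FALSE] %*% w + um[, -1, drop = FALSE] %*% w)
}

#' Discounted cost of one participant's resource use
#'
#' Surgical components (episode, theatre minutes, bed-days) accrue at
#' the year containing `surgery_month`; recurring items (readmissions,
#' A&E attendances, primary-care visits) are apportioned evenly across
#' the follow-up years, so each is discounted by the mean of the
#' yearly factors.
#'
#' @param record a one-row `participant_data` data frame (or list with
#'   the same fields).
#' @param costs a [unit_cost_table()].
#' @param rate annual discount rate.
#' @param followup_months trial follow-up horizon in months.
#' @return A list of class `cost_profile`: `total` and an itemised
#'   `components` vector (GBP, discounted).
#' @export
participant_cost <- function(record, costs, rate = 0.035,
                             followup_months = 24) {
  validate_unit_costs(costs)
  comp <- cost_components(as.data.frame(record[c(
    "had_surgery", "surgery_month", "theatre_minutes", "stay_days",
    "readmissions", "ae_attendances", "primary_care_visits")]),
    costs, rate, followup_months)
  structure(list(
    id = if (!is.null(record$id)) record$id else NA,
    total = sum(comp[1, ]),
    components = comp[1, ]
  ), class = "cost_profile")
}

#' @noRd
cost_components <- function(df, costs, rate, followup_months) {
  n <- nrow(df)
  surg <- as.numeric(df$had_surgery)
  syear <- rep(1, n)
  has <- surg > 0 & !is.na(df$surgery_month)
  syear[has] <- year_of_month(pmin(df$surgery_month[has], followup_months))
  dsurg <- annual_discount_factor(syear, rate)
  years <- seq_len(year_of_month(followup_months))
  drec <- mean(annual_discount_factor(years, rate))
  cbind(
    surgery_episode = surg * costs[["surgery_episode"]] * dsurg,
    theatre = surg * df$theatre_minutes * costs[["theatre_minute"]] * dsurg,
    stay = surg * df$stay_days * costs[["bed_day"]] * dsurg,
    readmission = df$readmissions * costs[["readmission_episode"]] * drec,
    ae = df$ae_attendances * costs[["ae_attendance"]] * drec,
    primary_care = df$primary_care_visits * costs[["primary_care_visit"]] * drec
  )
}

#' Per-participant discounted total costs for a cohort (vectorised)
#'
#' @inheritParams participant_cost
#' @param data a `participant_data` data frame.
#' @return Numeric vector of discounted total costs (GBP), one per row.
#' @export
cohort_costs <- function(data, costs, rate = 0.035, followup_months = 24) {
  validate_unit_costs(costs)
  rowSums(cost_components(data, costs, rate, followup_months))
}

#' @export
print.cost_profile <- function(x, ...) {
  cat(sprintf("Participant cost: %.2f GBP\n", x$total))
  print(round(x$components, 2))
  invisible(x)
}
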