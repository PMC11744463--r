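# Shared fixtures, built in code.

# small cohort for fast unit tests
small_params <- function(seed = 1L, ...) {
  trial_params(n_per_arm = 60L, n_centres = 5L, seed = seed, ...)
}

fixture_costs <- function() load_unit_costs("unit_costs_synthetic")

# unit-cost table where only one item is priced
one_item_costs <- function(item, price) {
  x <- stats::setNames(rep(0, 6),
                       c("surgery_episode", "theatre_minute", "bed_day",
                         "readmission_episode", "ae_attendance",
                         "primary_care_visit"))
  x[item] <- price
  do.call(unit_cost_table, as.list(x))
}

# life table with a constant annual mortality probability
flat_life_table <- function(q, ages = 18:120) {
  structure(
    rbind(data.frame(age = ages, sex = "F", qx = q),
          data.frame(age = ages, sex = "M", qx = q)),
    class = c("life_table", "data.frame"))
}

zero_mortality_table <- function() flat_life_table(0)

# fraction of post-baseline utility cells that are missing
missing_fraction <- function(data) {
  ucols <- setdiff(grep("^util_", names(data), value = TRUE), "util_0")
  mean(is.na(as.matrix(data[ucols])))
}
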