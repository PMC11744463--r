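# Synthetic trial-data generator.
#
# Emulates the statistical structure of a two-arm (laparoscopic
# cholecystectomy, LC, versus conservative management, CM) multicentre
# randomised trial with 24-month follow-up: SF-6D-style utility
# trajectories with a transient post-operative decrement, cumulative
# surgical uptake differing by arm, right-skewed waiting times, and
# hospital/primary-care resource use.

#' Parameters of the synthetic trial generator
#'
#' Builds and validates the parameter set driving [generate_cohort()].
#' Defaults reproduce the margins of the emulated trial: 217
#' participants per arm across 20 centres, mean age 50.5 years, 71%
#' women, cumulative cholecystectomy uptake of 70.5% (LC) and 29.5%
#' (CM) by month 24, theatre time 72(42) vs 83(49) minutes, hospital
#' stay 0.63(1.3) vs 1.4(3.4) days and readmission proportions 9.7% vs
#' 12.9%.
#'
#' Utility trajectories are piecewise-constant latent means plus
#' Gaussian noise truncated to the SF-6D range \eqn{[-0.59, 1]}: each
#' participant sits at their baseline utility until surgery (if any),
#' drops by `surgery_dip_depth` for `surgery_dip_duration` months after
#' the operation, then settles at baseline plus `surgery_benefit`
#' (plus `arm_utility_effect` in the LC arm). Months from randomisation
#' to surgery follow a gamma distribution truncated at 24 months.
#'
#' @param n_per_arm participants per arm.
#' @param n_centres number of recruiting centres; participants are
#'   assigned uniformly.
#' @param age_mean,age_sd age distribution (years) at randomisation.
#' @param prop_female proportion of women.
#' @param visit_schedule utility measurement times in months from
#'   randomisation; strictly increasing, starting at 0.
#' @param baseline_utility_mean,baseline_utility_sd baseline SF-6D
#'   utility distribution (truncated to the instrument range).
#' @param utility_noise_sd s.d. of visit-level Gaussian noise around the
#'   latent trajectory.
#' @param arm_utility_effect LC-minus-CM difference in post-surgery
#'   steady-state utility.
#' @param surgery_benefit post-recovery utility gain over baseline,
#'   common to both arms.
#' @param surgery_dip_depth,surgery_dip_duration size (utility units)
#'   and length (months) of the transient post-operative utility dip.
#' @param uptake_LC,uptake_CM cumulative probability of cholecystectomy
#'   by month 24, per arm.
#' @param waiting_time_params list with elements `LC` and `CM`, each
#'   `c(shape=, scale=)` of the gamma months-to-surgery distribution
#'   (truncated at 24).
#' @param resource_params list of per-arm resource-use parameters; see
#'   defaults for the expected structure (gamma mean/sd for theatre
#'   minutes and stay days, Bernoulli probability for readmission,
#'   Poisson rates for A&E attendances and primary-care visits over the
#'   follow-up).
#' @param centre_sd s.d. (log scale) of the mean-one multiplicative
#'   centre effect on primary-care visit intensity.
#' @param missing_rate default post-baseline utility missingness used by
#'   [apply_missingness()] callers.
#' @param unit_cost_ref identifier of the bundled unit-cost fixture.
#' @param seed integer RNG seed; all generation is deterministic given
#'   the full parameter set.
#' @return An object of class `trial_params` (a validated list).
#' @seealso [generate_cohort()], [apply_missingness()], [truth_summary()]
#' @export
trial_params <- function(n_per_arm = 217L,
                         n_centres = 20L,
                         age_mean = 50.5, age_sd = 11,
                         prop_female = 0.71,
                         visit_schedule = c(0, 3, 6, 12, 18, 24),
                         baseline_utility_mean = 0.70,
                         baseline_utility_sd = 0.12,
                         utility_noise_sd = 0.10,
                         arm_utility_effect = 0,
                         surgery_benefit = 0.03,
                         surgery_dip_depth = 0.10,
                         surgery_dip_duration = 2,
                         uptake_LC = 0.705, uptake_CM = 0.295,
                         waiting_time_params = list(
                           LC = c(shape = 1.5, scale = 4),
                           CM = c(shape = 1.5, scale = 8)
                         ),
                         resource_params = list(
                           theatre_minutes = list(LC = c(mean = 72, sd = 42),
                                                  CM = c(mean = 83, sd = 49)),
                           stay_days = list(LC = c(mean = 0.63, sd = 1.3),
                                            CM = c(mean = 1.4, sd = 3.4)),
                           readmission_prob = c(LC = 0.097, CM = 0.129),
                           ae_rate = c(LC = 0.221, CM = 0.469),
                           primary_care_rate = c(LC = 6, CM = 6)
                         ),
                         centre_sd = 0.2,
                         missing_rate = 0.2,
                         unit_cost_ref = "unit_costs_synthetic",
                         seed = 1L) {
  p <- list(
    n_per_arm = as.integer(n_per_arm), n_centres = as.integer(n_centres),
    age_mean = age_mean, age_sd = age_sd, prop_female = prop_female,
    visit_schedule = visit_schedule,
    baseline_utility_mean = baseline_utility_mean,
    baseline_utility_sd = baseline_utility_sd,
    utility_noise_sd = utility_noise_sd,
    arm_utility_effect = arm_utility_effect,
    surgery_benefit = surgery_benefit,
    surgery_dip_depth = surgery_dip_depth,
    surgery_dip_duration = surgery_dip_duration,
    uptake_LC = uptake_LC, uptake_CM = uptake_CM,
    waiting_time_params = waiting_time_params,
    resource_params = resource_params,
    centre_sd = centre_sd,
    missing_rate = missing_rate,
    unit_cost_ref = unit_cost_ref,
    seed = as.integer(seed)
  )
  validate_trial_params(p)
  structure(p, class = "trial_params")
}

#' @noRd
validate_trial_params <- function(p) {
  check_that(p$n_per_arm >= 1, "n_per_arm", "must be >= 1")
  check_that(p$n_centres >= 1, "n_centres", "must be >= 1")
  check_that(p$prop_female >= 0 && p$prop_female <= 1, "prop_female",
             "must lie in [0, 1]")
  vs <- p$visit_schedule
  check_that(length(vs) >= 2 && vs[1] == 0 && all(diff(vs) > 0),
             "visit_schedule",
             "must be strictly increasing and start at 0")
  check_that(p$age_sd >= 0, "age_sd", "must be >= 0")
  check_that(p$baseline_utility_sd >= 0, "baseline_utility_sd",
             "must be >= 0")
  check_that(p$utility_noise_sd >= 0, "utility_noise_sd", "must be >= 0")
  check_that(p$uptake_LC >= 0 && p$uptake_LC <= 1, "uptake_LC",
             "must lie in [0, 1]")
  check_that(p$uptake_CM >= 0 && p$uptake_CM <= 1, "uptake_CM",
             "must lie in [0, 1]")
  check_that(p$surgery_dip_duration >= 0, "surgery_dip_duration",
             "must be >= 0")
  for (arm in c("LC", "CM")) {
    w <- p$waiting_time_params[[arm]]
    check_that(!is.null(w) && all(w[c("shape", "scale")] > 0),
               "waiting_time_params",
               sprintf("gamma shape/scale for arm %s must be > 0", arm))
  }
  check_that(p$missing_rate >= 0 && p$missing_rate < 1, "missing_rate",
             "must lie in [0, 1)")
  check_that(p$centre_sd >= 0, "centre_sd", "must be >= 0")
  invisible(TRUE)
}

#' @noRd
util_colnames <- function(visit_schedule) {
  paste0("util_", visit_schedule)
}

#' Months-to-surgery sampler: gamma truncated at 24 months
#' @noRd
rwait <- function(n, shape, scale, cap = 24) {
  pcap <- stats::pgamma(cap, shape = shape, scale = scale)
  u <- stats::runif(n) * pcap
  pmin(stats::qgamma(u, shape = shape, scale = scale), cap)
}

#' Gamma sampler parameterised by mean and s.d.
#' @noRd
rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a complete synthetic trial cohort
#'
#' Draws `2 * n_per_arm` participant records (no missingness) under the
#' generator described in [trial_params()]. The result is a data frame
#' with one row per participant: identifiers and covariates (`id`,
#' `arm`, `centre`, `age`, `sex`, `baseline_utility`), surgery events
#' (`had_surgery`, `surgery_month`), resource use (`theatre_minutes`,
#' `stay_days`, `readmissions`, `ae_attendances`,
#' `primary_care_visits`) and one utility column per scheduled visit
#' (`util_0`, `util_3`, ...). `util_0` equals `baseline_utility`.
#'
#' @param params a [trial_params()] object.
#' @return A data frame of class `participant_data` carrying `params`
#'   as an attribute. Deterministic given `params` (including its seed).
#' @examples
#' cohort <- generate_cohort(trial_params(n_per_arm = 50, seed = 42))
#' table(cohort$arm, cohort$had_surgery)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "trial_params")) params <- do.call(trial_params, params)
  validate_trial_params(params)
  p <- params
  n <- 2L * p$n_per_arm
  with_seed(p$seed, {
    arm <- rep(c("LC", "CM"), each = p$n_per_arm)
    centre <- sample.int(p$n_centres, n, replace = TRUE)
    # mean-one multiplicative centre effect on primary-care intensity
    centre_mult <- exp(stats::rnorm(p$n_centres, -p$centre_sd^2 / 2, p$centre_sd))
    age <- pmax(18, stats::rnorm(n, p$age_mean, p$age_sd))
    sex <- ifelse(stats::runif(n) < p$prop_female, "F", "M")
    baseline <- rtnorm(n, p$baseline_utility_mean, p$baseline_utility_sd)

    uptake <- ifelse(arm == "LC", p$uptake_LC, p$uptake_CM)
    had_surgery <- stats::runif(n) < uptake
    surgery_month <- rep(NA_real_, n)
    for (a in c("LC", "CM")) {
      idx <- which(had_surgery & arm == a)
      w <- p$waiting_time_params[[a]]
      surgery_month[idx] <- rwait(length(idx), w[["shape"]], w[["scale"]],
                                  cap = max(p$visit_schedule))
    }

    rp <- p$resource_params
    theatre <- stay <- numeric(n)
    for (a in c("LC", "CM")) {
      idx <- which(had_surgery & arm == a)
      th <- rp$theatre_minutes[[a]]
      st <- rp$stay_days[[a]]
      theatre[idx] <- rgamma_ms(length(idx), th[["mean"]], th[["sd"]])
      stay[idx] <- rgamma_ms(length(idx), st[["mean"]], st[["sd"]])
    }
    readm <- stats::rbinom(n, 1L, rp$readmission_prob[arm])
    ae <- stats::rpois(n, rp$ae_rate[arm])
    gp <- stats::rpois(n, rp$primary_care_rate[arm] * centre_mult[centre])

    # latent utility mean at each visit, then truncated Gaussian noise
    steady <- p$surgery_benefit + ifelse(arm == "LC", p$arm_utility_effect, 0)
    um <- matrix(NA_real_, n, length(p$visit_schedule),
                 dimnames = list(NULL, util_colnames(p$visit_schedule)))
    um[, 1] <- baseline
    for (j in seq_along(p$visit_schedule)[-1]) {
      t <- p$visit_schedule[j]
      offset <- numeric(n)
      post <- had_surgery & !is.na(surgery_month) & surgery_month <= t
      dip <- post & (t < surgery_month + p$surgery_dip_duration)
      offset[dip] <- -p$surgery_dip_depth
      offset[post & !dip] <- steady[post & !dip]
      um[, j] <- rtnorm(n, baseline + offset, p$utility_noise_sd)
    }

    out <- data.frame(
      id = seq_len(n), arm = arm, centre = centre, age = age, sex = sex,
      baseline_utility = baseline, had_surgery = had_surgery,
      surgery_month = surgery_month, theatre_minutes = theatre,
      stay_days = stay, readmissions = readm, ae_attendances = ae,
      primary_care_visits = gp,
      stringsAsFactors = FALSE
    )
    out <- cbind(out, as.data.frame(um))
    attr(out, "params") <- p
    class(out) <- c("participant_data", "data.frame")
    out
  })
}

#' Mask post-baseline utility visits
#'
#' Introduces missingness into the utility trajectory columns of a
#' cohort. Under `MCAR` every post-baseline entry is masked
#' independently with probability `rate`. Under `MAR` the masking
#' probability follows a logistic model in the observed baseline
#' utility and arm (coefficients -2 on baseline utility and +0.3 for
#' the CM arm; the intercept is solved numerically so the expected
#' overall rate equals `rate`). The baseline visit is never masked.
#'
#' @param data a `participant_data` data frame.
#' @param mechanism `"MAR"` (default) or `"MCAR"`.
#' @param rate target missingness proportion among post-baseline
#'   entries, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return `data` with `NA`s in masked utility cells.
#' @export
apply_missingness <- function(data, mechanism = c("MAR", "MCAR"),
                              rate, seed) {
  mechanism <- match.arg(mechanism)
  check_that(is.numeric(rate) && rate >= 0 && rate < 1, "rate",
             "must lie in [0, 1)")
  ucols <- grep("^util_", names(data), value = TRUE)
  post <- setdiff(ucols, "util_0")
  if (rate == 0 || length(post) == 0) return(data)
  with_seed(seed, {
    n <- nrow(data)
    if (mechanism == "MCAR") {
      pmat <- matrix(rate, n, length(post))
    } else {
      lin <- -2 * data$baseline_utility + 0.3 * (data$arm == "CM")
      f <- function(a) mean(stats::plogis(a + lin)) - rate
      a <- stats::uniroot(f, c(-30, 30))$root
      pmat <- matrix(stats::plogis(a + lin), n, length(post))
    }
    mask <- matrix(stats::runif(n * length(post)), n) < pmat
    for (j in seq_along(post)) data[[post[j]]][mask[, j]] <- NA_real_
    data
  })
}

#' Closed-form expected costs and QALYs implied by generator parameters
#'
#' Computes the per-arm expected discounted cost and QALY analytically
#' (expectation over surgical uptake, truncated-gamma waiting times,
#' the post-operative utility dip and the resource-use means), for use
#' as ground truth in parameter-recovery simulations. The QALY
#' expectation exploits linearity of the trapezoidal
#' area-under-the-curve rule: it equals the discounted AUC of the
#' expected utility at each visit, where visit-level expectations
#' integrate the truncated-normal noise mean over the baseline-utility
#' distribution (one-dimensional quadrature).
#'
#' @param params a [trial_params()] object.
#' @param costs a [unit_cost_table()]; defaults to the fixture named by
#'   `params$unit_cost_ref`.
#' @param discount_rate annual discount rate applied beyond year one.
#' @return An object of class `truth_summary`: per-arm expected cost
#'   and QALY, and their CM-minus-LC differences `true_delta_cost`,
#'   `true_delta_qaly`.
#' @export
truth_summary <- function(params, costs = NULL, discount_rate = 0.035) {
  if (!inherits(params, "trial_params")) params <- do.call(trial_params, params)
  validate_trial_params(params)
  p <- params
  if (is.null(costs)) costs <- load_unit_costs(p$unit_cost_ref)
  validate_unit_costs(costs)

  vs <- p$visit_schedule
  horizon <- max(vs)
  d1 <- annual_discount_factor(1, discount_rate)
  dfac <- function(y) annual_discount_factor(y, discount_rate)

  # truncated-gamma waiting-time CDF per arm
  Fwait <- function(x, arm) {
    w <- p$waiting_time_params[[arm]]
    pcap <- stats::pgamma(horizon, shape = w[["shape"]], scale = w[["scale"]])
    ifelse(x <= 0, 0,
           pmin(stats::pgamma(pmin(x, horizon), shape = w[["shape"]],
                              scale = w[["scale"]]) / pcap, 1))
  }

  # density of the truncated-normal baseline distribution
  bz <- stats::pnorm(UTILITY_CEIL, p$baseline_utility_mean, p$baseline_utility_sd) -
    stats::pnorm(UTILITY_FLOOR, p$baseline_utility_mean, p$baseline_utility_sd)
  fbase <- function(b) {
    stats::dnorm(b, p$baseline_utility_mean, p$baseline_utility_sd) / bz
  }

  eu_visit <- function(t, arm) {
    if (t == 0) {
      return(etnorm(p$baseline_utility_mean, p$baseline_utility_sd))
    }
    up <- if (arm == "LC") p$uptake_LC else p$uptake_CM
    steady <- p$surgery_benefit + if (arm == "LC") p$arm_utility_effect else 0
    w_pre <- (1 - up) + up * (1 - Fwait(t, arm))
    w_dip <- up * (Fwait(t, arm) - Fwait(t - p$surgery_dip_duration, arm))
    w_std <- up * Fwait(t - p$surgery_dip_duration, arm)
    integrand <- function(b) {
      fbase(b) * (w_pre * etnorm(b, p$utility_noise_sd) +
                    w_dip * etnorm(b - p$surgery_dip_depth, p$utility_noise_sd) +
                    w_std * etnorm(b + steady, p$utility_noise_sd))
    }
    stats::integrate(integrand, UTILITY_FLOOR, UTILITY_CEIL,
                     rel.tol = 1e-9)$value
  }

  arm_truth <- function(arm) {
    eu <- vapply(vs, eu_visit, numeric(1), arm = arm)
    qaly <- auc_qaly(vs, eu, rate = discount_rate)$discounted

    up <- if (arm == "LC") p$uptake_LC else p$uptake_CM
    rp <- p$resource_params
    th <- rp$theatre_minutes[[arm]][["mean"]]
    st <- rp$stay_days[[arm]][["mean"]]
    # expected discount factor at the year of surgery
    e_dsurg <- Fwait(12, arm) * dfac(1) + (1 - Fwait(12, arm)) * dfac(2)
    surg_cost <- up * (costs[["surgery_episode"]] +
                         th * costs[["theatre_minute"]] +
                         st * costs[["bed_day"]]) * e_dsurg
    # recurring items apportioned evenly over follow-up years
    years <- seq_len(year_of_month(horizon))
    d_rec <- mean(vapply(years, dfac, numeric(1)))
    rec_cost <- (rp$readmission_prob[[arm]] * costs[["readmission_episode"]] +
                   rp$ae_rate[[arm]] * costs[["ae_attendance"]] +
                   rp$primary_care_rate[[arm]] * costs[["primary_care_visit"]]) * d_rec
    list(qaly = qaly, cost = surg_cost + rec_cost)
  }

  lc <- arm_truth("LC")
  cm <- arm_truth("CM")
  structure(list(
    qaly_LC = lc$qaly, qaly_CM = cm$qaly,
    cost_LC = lc$cost, cost_CM = cm$cost,
    true_delta_qaly = cm$qaly - lc$qaly,
    true_delta_cost = cm$cost - lc$cost,
    discount_rate = discount_rate
  ), class = "truth_summary")
}

#' @export
print.truth_summary <- function(x, ...) {
  cat("Generator-implied expectations (CM - LC orientation)\n")
  cat(sprintf("  cost: LC %.2f  CM %.2f  delta %+.2f GBP\n",
              x$cost_LC, x$cost_CM, x$true_delta_cost))
  cat(sprintf("  QALY: LC %.4f  CM %.4f  delta %+.4f\n",
              x$qaly_LC, x$qaly_CM, x$true_delta_qaly))
  invisible(x)
}

#' Write / read participant data as CSV
#'
#' Missing utility entries are encoded as empty fields. The header is
#' the column set documented in [generate_cohort()].
#' @param data a `participant_data` data frame.
#' @param path file path.
#' @return `read_participant_csv` returns a `participant_data` data
#'   frame.
#' @export
write_participant_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_participant_csv
#' @export
read_participant_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "arm", "centre", "age", "sex", "baseline_utility",
                "had_surgery", "surgery_month", "theatre_minutes",
                "stay_days", "readmissions", "ae_attendances",
                "primary_care_visits", "util_0")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("participant CSV lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$had_surgery <- as.logical(df$had_surgery)
  class(df) <- c("participant_data", "data.frame")
  df
}
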