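# Markov cohort model: monthly cycles over a 10-year horizon.
# States: NoSurgery -> Recovery tunnel (fixed dwell, sub-state encoded)
# -> SymptomsResolved / SymptomsPersist; Death absorbs from everywhere
# via life-table mortality. The cohort enters in NoSurgery.

MARKOV_STATES <- c("NoSurgery", "RecoveryTunnel", "SymptomsResolved",
                   "SymptomsPersist", "Death")

#' Convert an annual probability to a monthly probability
#'
#' Constant-hazard conversion: \eqn{1 - (1 - p)^{1/12}}.
#'
#' @param p_annual probability in `[0, 1]`.
#' @return Monthly probability. Vectorised.
#' @export
monthly_from_annual_prob <- function(p_annual) {
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_annual)^(1 / 12)
}

#' Load a life table from CSV
#'
#' Expects an ONS-style layout with columns `age`, `sex` (`F`/`M`) and
#' `qx` (annual mortality probability). The bundled
#' `life_table_synthetic` fixture covers ages 40-100 for both sexes
#' with Gompertz-shaped, age-monotone probabilities; it is synthetic,
#' not a national life table.
#'
#' @param ref path or bundled fixture name (without extension).
#' @return A data frame of class `life_table`.
#' @export
load_life_table <- function(ref = "life_table_synthetic") {
  path <- if (file.exists(ref)) ref else
    system.file("extdata", paste0(ref, ".csv"), package = "cholecea")
  if (!nzchar(path) || !file.exists(path)) {
    stop("life table not found: ", ref, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age", "sex", "qx") %in% names(df)))
  if (any(df$qx < 0 | df$qx > 1)) {
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  }
  class(df) <- c("life_table", "data.frame")
  df
}

#' Sex-weighted monthly mortality at a given age
#'
#' Annual probability = `prop_female * qx_F + (1 - prop_female) * qx_M`
#' at `floor(age)`, then converted by [monthly_from_annual_prob()].
#'
#' @param table a [load_life_table()] data frame.
#' @param age age in years (within the table range).
#' @param prop_female cohort proportion of women.
#' @return Monthly death probability.
#' @export
mortality_lookup <- function(table, age, prop_female) {
  a <- floor(age)
  qf <- table$qx[table$age == a & table$sex == "F"]
  qm <- table$qx[table$age == a & table$sex == "M"]
  if (length(qf) != 1L || length(qm) != 1L) {
    stop(sprintf(
      "age %d outside life-table range; extend the table to cover it", a),
      call. = FALSE)
  }
  monthly_from_annual_prob(prop_female * qf + (1 - prop_female) * qm)
}

#' Specification of the Markov cohort model
#'
#' Defaults describe a cohort with mean age 50.5 years, 71% women,
#' monthly cycles over a 10-year horizon, entering in `NoSurgery`.
#' Surgery moves individuals into a fixed-dwell recovery tunnel with a
#' quality-of-life decrement and the surgical episode cost; on tunnel
#' exit symptoms resolve with probability `p_resolved`. By default the
#' resolved and persisting states carry the same utility. The monthly
#' surgery hazard over months 1-24 defaults to the constant schedule
#' whose cumulative uptake matches `uptake` (70.5% for LC, 29.5% for
#' CM); the post-month-24 hazard defaults to 0.
#'
#' @param strategy `"LC"` or `"CM"`.
#' @param horizon number of monthly cycles (default 120 = 10 years).
#' @param start_age cohort age at entry (years).
#' @param prop_female proportion of women (mortality mix).
#' @param uptake cumulative surgery probability by month 24 used to
#'   derive a constant hazard when `surgery_schedule` is `NULL`.
#' @param surgery_schedule optional length-24 vector of per-cycle
#'   surgery probabilities for months 1-24.
#' @param post24_hazard per-cycle surgery probability beyond month 24.
#' @param tunnel_months fixed dwell in the recovery tunnel.
#' @param p_resolved probability symptoms resolve on tunnel exit.
#' @param utilities named per-state annual utilities (`Death` must be
#'   0); the tunnel utility applies to every tunnel sub-state.
#' @param utility_schedule optional matrix (cycles x named states)
#'   overriding state utilities for its first `nrow` cycles, e.g.
#'   trial-informed, time-varying utilities up to month 48.
#' @param state_costs named per-state monthly costs in GBP (`Death`
#'   must be 0).
#' @param surgery_episode_cost GBP accrued on entry into the tunnel.
#' @param discount_rate annual discount rate (year one undiscounted).
#' @param life_table a [load_life_table()] data frame (default: the
#'   bundled synthetic fixture).
#' @param half_cycle apply a half-cycle correction (average of start-
#'   and end-of-cycle occupancy) to state accruals.
#' @return A validated list of class `markov_spec`.
#' @export
markov_spec <- function(strategy = c("LC", "CM"),
                        horizon = 120L,
                        start_age = 50.5,
                        prop_female = 0.71,
                        uptake = NULL,
                        surgery_schedule = NULL,
                        post24_hazard = 0,
                        tunnel_months = 1L,
                        p_resolved = 0.6,
                        utilities = c(NoSurgery = 0.70, RecoveryTunnel = 0.60,
                                      SymptomsResolved = 0.73,
                                      SymptomsPersist = 0.73, Death = 0),
                        utility_schedule = NULL,
                        state_costs = c(NoSurgery = 15, RecoveryTunnel = 30,
                                        SymptomsResolved = 5,
                                        SymptomsPersist = 15, Death = 0),
                        surgery_episode_cost = 2900,
                        discount_rate = 0.035,
                        life_table = NULL,
                        half_cycle = FALSE) {
  strategy <- match.arg(strategy)
  if (is.null(uptake)) uptake <- if (strategy == "LC") 0.705 else 0.295
  if (is.null(surgery_schedule)) {
    h <- 1 - (1 - uptake)^(1 / 24)
    surgery_schedule <- rep(h, 24)
  }
  if (is.null(life_table)) life_table <- load_life_table()
  s <- list(strategy = strategy, horizon = as.integer(horizon),
            start_age = start_age, prop_female = prop_female,
            surgery_schedule = surgery_schedule,
            post24_hazard = post24_hazard,
            tunnel_months = as.integer(tunnel_months),
            p_resolved = p_resolved, utilities = utilities,
            utility_schedule = utility_schedule,
            state_costs = state_costs,
            surgery_episode_cost = surgery_episode_cost,
            discount_rate = discount_rate, life_table = life_table,
            half_cycle = isTRUE(half_cycle))
  validate_markov_spec(s)
  structure(s, class = "markov_spec")
}

#' @noRd
validate_markov_spec <- function(s) {
  check_that(s$horizon >= 1, "horizon", "must be >= 1")
  check_that(s$tunnel_months >= 1, "tunnel_months", "must be >= 1")
  check_that(s$p_resolved >= 0 && s$p_resolved <= 1, "p_resolved",
             "must lie in [0, 1]")
  check_that(all(s$surgery_schedule >= 0 & s$surgery_schedule <= 1),
             "surgery_schedule", "per-cycle probabilities must lie in [0, 1]")
  check_that(s$post24_hazard >= 0 && s$post24_hazard <= 1, "post24_hazard",
             "must lie in [0, 1]")
  check_that(all(MARKOV_STATES %in% names(s$utilities)), "utilities",
             "must name every state")
  check_that(all(MARKOV_STATES %in% names(s$state_costs)), "state_costs",
             "must name every state")
  check_that(all(s$utilities >= UTILITY_FLOOR & s$utilities <= 1),
             "utilities", "must lie in [-0.59, 1]")
  check_that(s$utilities[["Death"]] == 0, "utilities", "Death must be 0")
  check_that(s$state_costs[["Death"]] == 0, "state_costs", "Death must be 0")
  check_that(all(s$state_costs >= 0), "state_costs", "must be >= 0")
  check_that(s$surgery_episode_cost >= 0, "surgery_episode_cost",
             "must be >= 0")
  check_that(s$discount_rate >= 0, "discount_rate", "must be >= 0")
  if (!is.null(s$utility_schedule)) {
    check_that(all(MARKOV_STATES %in% colnames(s$utility_schedule)),
               "utility_schedule", "columns must name every state")
  }
  invisible(TRUE)
}

#' Internal (expanded) state names: tunnel encoded as sub-states
#' @noRd
markov_substates <- function(spec) {
  c("NoSurgery", paste0("Recovery", seq_len(spec$tunnel_months)),
    "SymptomsResolved", "SymptomsPersist", "Death")
}

#' @noRd
surgery_hazard_at <- function(spec, cycle) {
  if (cycle <= length(spec$surgery_schedule)) {
    spec$surgery_schedule[cycle]
  } else {
    spec$post24_hazard
  }
}

#' Transition matrix for one cycle
#'
#' Rows/columns are the expanded sub-states (tunnel months as separate
#' sub-states so the dwell is exact). From `NoSurgery`: to the first
#' tunnel sub-state with the strategy's hazard at this cycle, to
#' `Death` with current mortality, remainder stays. Tunnel sub-states
#' advance deterministically (conditional on survival); the final one
#' exits to `SymptomsResolved` with `p_resolved`, else
#' `SymptomsPersist`. Resolved/persisting are absorbing except for
#' death. Every row sums to exactly 1.
#'
#' @param spec a [markov_spec()].
#' @param cycle cycle index in `[1, horizon]`.
#' @return A square stochastic matrix.
#' @export
transition_matrix <- function(spec, cycle) {
  if (cycle < 1 || cycle > spec$horizon) {
    stop("cycle must lie in [1, horizon]", call. = FALSE)
  }
  age <- spec$start_age + (cycle - 1) / 12
  q <- mortality_lookup(spec$life_table, age, spec$prop_female)
  h <- surgery_hazard_at(spec, cycle)
  if (h + q > 1) {
    stop(sprintf(
      "surgery hazard (%.4f) + mortality (%.4f) exceeds 1 at cycle %d",
      h, q, cycle), call. = FALSE)
  }
  st <- markov_substates(spec)
  S <- length(st)
  P <- matrix(0, S, S, dimnames = list(st, st))
  death <- S
  P["NoSurgery", "NoSurgery"] <- 1 - h - q
  P["NoSurgery", "Recovery1"] <- h
  P["NoSurgery", death] <- q
  d <- spec$tunnel_months
  for (k in seq_len(d)) {
    from <- paste0("Recovery", k)
    if (k < d) {
      P[from, paste0("Recovery", k + 1)] <- 1 - q
    } else {
      P[from, "SymptomsResolved"] <- (1 - q) * spec$p_resolved
      P[from, "SymptomsPersist"] <- (1 - q) * (1 - spec$p_resolved)
    }
    P[from, death] <- q
  }
  P["SymptomsResolved", "SymptomsResolved"] <- 1 - q
  P["SymptomsResolved", death] <- q
  P["SymptomsPersist", "SymptomsPersist"] <- 1 - q
  P["SymptomsPersist", death] <- q
  P["Death", death] <- 1
  P
}

#' @noRd
state_values_at <- function(spec, cycle, what = c("utilities", "state_costs")) {
  what <- match.arg(what)
  v <- spec[[what]]
  if (what == "utilities" && !is.null(spec$utility_schedule) &&
      cycle <= nrow(spec$utility_schedule)) {
    v[MARKOV_STATES] <- spec$utility_schedule[cycle, MARKOV_STATES]
  }
  st <- markov_substates(spec)
  out <- numeric(length(st))
  names(out) <- st
  out["NoSurgery"] <- v[["NoSurgery"]]
  out[grep("^Recovery", st)] <- v[["RecoveryTunnel"]]
  out["SymptomsResolved"] <- v[["SymptomsResolved"]]
  out["SymptomsPersist"] <- v[["SymptomsPersist"]]
  out["Death"] <- v[["Death"]]
  out
}

#' Run the Markov cohort
#'
#' Starts with full mass in `NoSurgery` and iterates the per-cycle
#' transition matrix. Per cycle the cohort accrues
#' `occupancy x state utility / 12`, discounted by the factor of the
#' year containing the cycle (year one undiscounted), and likewise for
#' state costs, plus the surgical episode cost on the flow into the
#' tunnel. Accrual uses start-of-cycle occupancy unless
#' `spec$half_cycle` averages start and end.
#'
#' @param spec a [markov_spec()].
#' @return An object of class `cohort_trace`: `occupancy` (cycle x
#'   collapsed state matrix, including cycle 0), per-cycle discounted
#'   `cost` and `qaly` streams, `total_cost`, `total_qaly`.
#' @export
run_cohort <- function(spec) {
  validate_markov_spec(spec)
  st <- markov_substates(spec)
  S <- length(st)
  H <- spec$horizon
  x <- numeric(S)
  names(x) <- st
  x["NoSurgery"] <- 1
  occ <- matrix(0, H + 1, length(MARKOV_STATES),
                dimnames = list(0:H, MARKOV_STATES))
  occ[1, ] <- collapse_states(x, spec)
  cost_cycle <- qaly_cycle <- numeric(H)
  for (k in seq_len(H)) {
    P <- transition_matrix(spec, k)
    fac <- annual_discount_factor(year_of_month(k), spec$discount_rate)
    u <- state_values_at(spec, k, "utilities")
    cst <- state_values_at(spec, k, "state_costs")
    x_new <- as.numeric(x %*% P)
    names(x_new) <- st
    occ_eff <- if (spec$half_cycle) (x + x_new) / 2 else x
    inflow_tunnel <- x[["NoSurgery"]] * P["NoSurgery", "Recovery1"]
    qaly_cycle[k] <- sum(occ_eff * u) / 12 * fac
    cost_cycle[k] <- (sum(occ_eff * cst) +
                        inflow_tunnel * spec$surgery_episode_cost) * fac
    x <- x_new
    occ[k + 1, ] <- collapse_states(x, spec)
  }
  structure(list(
    occupancy = occ, cost = cost_cycle, qaly = qaly_cycle,
    total_cost = sum(cost_cycle), total_qaly = sum(qaly_cycle),
    spec = spec
  ), class = "cohort_trace")
}

#' @noRd
collapse_states <- function(x, spec) {
  c(NoSurgery = unname(x[["NoSurgery"]]),
    RecoveryTunnel = sum(x[grep("^Recovery", names(x))]),
    SymptomsResolved = unname(x[["SymptomsResolved"]]),
    SymptomsPersist = unname(x[["SymptomsPersist"]]),
    Death = unname(x[["Death"]]))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Markov cohort (%s), %d monthly cycles\n",
              x$spec$strategy, x$spec$horizon))
  cat(sprintf("  discounted totals: cost %.2f GBP, QALYs %.4f\n",
              x$total_cost, x$total_qaly))
  cat(sprintf("  final occupancy: %s\n",
              paste(sprintf("%s %.3f", colnames(x$occupancy),
                            x$occupancy[nrow(x$occupancy), ]),
                    collapse = ", ")))
  invisible(x)
}

#' Deterministic strategy comparison
#'
#' Runs both cohorts and reports CM-minus-LC incrementals with the
#' ICER.
#'
#' @param spec_LC,spec_CM [markov_spec()] objects differing only in
#'   strategy-level parameters; horizons must match.
#' @return A list of class `model_comparison`: per-strategy traces,
#'   `delta_cost`, `delta_qaly`, `icer`.
#' @export
compare_strategies <- function(spec_LC, spec_CM) {
  if (spec_LC$horizon != spec_CM$horizon) {
    stop("strategy specs have mismatched horizons", call. = FALSE)
  }
  tr_lc <- run_cohort(spec_LC)
  tr_cm <- run_cohort(spec_CM)
  dc <- tr_cm$total_cost - tr_lc$total_cost
  dq <- tr_cm$total_qaly - tr_lc$total_qaly
  structure(list(
    LC = tr_lc, CM = tr_cm,
    delta_cost = dc, delta_qaly = dq,
    icer = compute_icer(dc, dq)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Markov model comparison (CM minus LC)\n")
  cat(sprintf("  LC: cost %.2f, QALY %.4f\n",
              x$LC$total_cost, x$LC$total_qaly))
  cat(sprintf("  CM: cost %.2f, QALY %.4f\n",
              x$CM$total_cost, x$CM$total_qaly))
  cat(sprintf("  delta cost %+.2f GBP, delta QALY %+.4f\n",
              x$delta_cost, x$delta_qaly))
  print(x$icer)
  invisible(x)
}

#' Microsimulation oracle for the cohort model
#'
#' Simulates individuals through the same per-cycle transition
#' probabilities as [run_cohort()] and accrues discounted costs and
#' QALYs per individual, as an independent validation of the cohort
#' expectations.
#'
#' @param spec a [markov_spec()].
#' @param n_individuals number of simulated individuals (>= 1000).
#' @param seed integer RNG seed.
#' @return List of class `microsim_result`: `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly`, `n`.
#' @export
microsim_oracle <- function(spec, n_individuals = 100000L, seed = 1L) {
  validate_markov_spec(spec)
  check_that(n_individuals >= 1000, "n_individuals", "must be >= 1000")
  st <- markov_substates(spec)
  S <- length(st)
  i_ns <- 1L
  i_rec1 <- 2L
  i_res <- S - 2L
  i_per <- S - 1L
  i_dth <- S
  with_seed(seed, {
    n <- as.integer(n_individuals)
    state <- rep(i_ns, n)
    cost <- qaly <- numeric(n)
    for (k in seq_len(spec$horizon)) {
      age <- spec$start_age + (k - 1) / 12
      q <- mortality_lookup(spec$life_table, age, spec$prop_female)
      h <- surgery_hazard_at(spec, k)
      if (h + q > 1) {
        stop(sprintf("surgery hazard + mortality exceeds 1 at cycle %d", k),
             call. = FALSE)
      }
      fac <- annual_discount_factor(year_of_month(k), spec$discount_rate)
      u <- state_values_at(spec, k, "utilities")
      cst <- state_values_at(spec, k, "state_costs")
      # start-of-cycle accrual
      qaly <- qaly + u[state] / 12 * fac
      cost <- cost + cst[state] * fac
      r <- stats::runif(n)
      new_state <- state
      ns <- state == i_ns
      new_state[ns & r < h] <- i_rec1
      new_state[ns & r >= h & r < h + q] <- i_dth
      for (kk in seq_len(spec$tunnel_months)) {
        ik <- 1L + kk
        in_t <- state == ik
        if (!any(in_t)) next
        dead <- in_t & r < q
        new_state[dead] <- i_dth
        alive <- in_t & !dead
        if (kk < spec$tunnel_months) {
          new_state[alive] <- ik + 1L
        } else {
          # second uniform keeps the exit split independent of survival
          r2 <- stats::runif(n)
          new_state[alive & r2 < spec$p_resolved] <- i_res
          new_state[alive & r2 >= spec$p_resolved] <- i_per
        }
      }
      for (ia in c(i_res, i_per)) {
        in_a <- state == ia
        new_state[in_a & r < q] <- i_dth
      }
      cost <- cost + (state == i_ns & new_state == i_rec1) *
        spec$surgery_episode_cost * fac
      state <- new_state
    }
    structure(list(
      mean_cost = mean(cost), mean_qaly = mean(qaly),
      se_cost = stats::sd(cost) / sqrt(n),
      se_qaly = stats::sd(qaly) / sqrt(n),
      n = n
    ), class = "microsim_result")
  })
}
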