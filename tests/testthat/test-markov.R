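# Markov cohort model: probability conversions, transition structure,
# cohort accounting, strategy comparison, PSA and the microsimulation
# oracle.

test_that("annual-to-monthly probability conversion is the constant-hazard form", {
  expect_equal(monthly_from_annual_prob(0), 0)
  expect_equal(monthly_from_annual_prob(1), 1)
  expect_equal(monthly_from_annual_prob(0.12), 1 - 0.88^(1 / 12))
  expect_equal(monthly_from_annual_prob(0.12), 0.01060, tolerance = 1e-3)
  expect_error(monthly_from_annual_prob(1.1), "\\[0, 1\\]")
})

test_that("mortality lookup mixes sexes then converts to monthly", {
  lt <- rbind(data.frame(age = 50:60, sex = "F", qx = 0.01),
              data.frame(age = 50:60, sex = "M", qx = 0.03))
  class(lt) <- c("life_table", "data.frame")
  q <- mortality_lookup(lt, 55.7, 0.71)
  annual <- 0.71 * 0.01 + 0.29 * 0.03
  expect_equal(q, 1 - (1 - annual)^(1 / 12))
  expect_equal(q, 0.001327, tolerance = 1e-2)
  # degenerate mix: independent of the sex proportion
  flat <- flat_life_table(0.02, 50:60)
  expect_equal(mortality_lookup(flat, 55, 0.71),
               mortality_lookup(flat, 55, 0.2))
  expect_equal(mortality_lookup(flat_life_table(0, 50:60), 55, 0.5), 0)
  expect_error(mortality_lookup(lt, 80, 0.71), "extend")
})

test_that("transition matrices are row-stochastic with the promised structure", {
  spec <- markov_spec("LC", life_table = load_life_table())
  P <- transition_matrix(spec, 1)
  expect_equal(unname(P["Death", ]), c(0, 0, 0, 0, 1))
  expect_true(all(P >= 0 & P <= 1))
  for (k in c(1, 24, 25, 120)) {
    expect_equal(unname(rowSums(transition_matrix(spec, k))),
                 rep(1, nrow(P)), tolerance = 1e-15)
  }
  # no events: the NoSurgery row is the identity row
  quiet <- markov_spec("CM", uptake = 0, life_table = zero_mortality_table())
  P0 <- transition_matrix(quiet, 1)
  expect_equal(unname(P0["NoSurgery", ]),
               as.numeric(colnames(P0) == "NoSurgery"))
  expect_error(transition_matrix(spec, 0), "cycle")
  # impossible hazard + mortality flagged as a specification error
  bad <- markov_spec("LC", surgery_schedule = rep(0.9999, 24),
                     life_table = flat_life_table(0.9))
  expect_error(run_cohort(bad), "exceeds 1")
})

test_that("cohort totals match closed forms", {
  # alive and well for a decade: 10 QALYs
  well <- markov_spec("LC", uptake = 0,
                      utilities = c(NoSurgery = 1, RecoveryTunnel = 1,
                                    SymptomsResolved = 1,
                                    SymptomsPersist = 1, Death = 0),
                      state_costs = c(NoSurgery = 0, RecoveryTunnel = 0,
                                      SymptomsResolved = 0,
                                      SymptomsPersist = 0, Death = 0),
                      surgery_episode_cost = 0,
                      discount_rate = 0,
                      life_table = zero_mortality_table())
  tr <- run_cohort(well)
  expect_equal(tr$total_qaly, 10, tolerance = 1e-9)
  expect_equal(tr$total_cost, 0)
  # constant monthly mortality p: QALY = (1/12) * sum (1-p)^(k-1)
  q_ann <- 0.12
  p <- 1 - (1 - q_ann)^(1 / 12)
  dying <- markov_spec("LC", uptake = 0,
                       utilities = c(NoSurgery = 1, RecoveryTunnel = 1,
                                     SymptomsResolved = 1,
                                     SymptomsPersist = 1, Death = 0),
                       state_costs = c(NoSurgery = 0, RecoveryTunnel = 0,
                                       SymptomsResolved = 0,
                                       SymptomsPersist = 0, Death = 0),
                       surgery_episode_cost = 0, discount_rate = 0,
                       life_table = flat_life_table(q_ann))
  tr2 <- run_cohort(dying)
  expect_equal(tr2$total_qaly, sum((1 - p)^(0:119)) / 12, tolerance = 1e-10)
})

test_that("occupancy is conserved and death is monotone", {
  for (strategy in c("LC", "CM")) {
    tr <- run_cohort(markov_spec(strategy, life_table = load_life_table()))
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
    expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
    expect_equal(tr$total_cost, sum(tr$cost))
    expect_equal(tr$total_qaly, sum(tr$qaly))
  }
})

test_that("the tunnel dwell is exact", {
  spec <- markov_spec("LC", tunnel_months = 3,
                      surgery_schedule = c(1, rep(0, 23)),
                      life_table = zero_mortality_table(), p_resolved = 1)
  tr <- run_cohort(spec)
  occ <- tr$occupancy
  # whole cohort operated in cycle 1, dwells exactly 3 cycles, then resolves
  expect_equal(unname(occ["1", "RecoveryTunnel"]), 1)
  expect_equal(unname(occ["3", "RecoveryTunnel"]), 1)
  expect_equal(unname(occ["4", "RecoveryTunnel"]), 0)
  expect_equal(unname(occ["4", "SymptomsResolved"]), 1)
})

test_that("strategy comparison reacts in the expected directions", {
  lt <- load_life_table()
  sl <- markov_spec("LC", life_table = lt)
  sc <- markov_spec("CM", life_table = lt)
  # identical specs (same strategy parameters): zero deltas
  sc_same <- markov_spec("CM", uptake = 0.705, life_table = lt)
  same <- compare_strategies(sl, sc_same)
  expect_equal(same$delta_cost, 0, tolerance = 1e-10)
  expect_equal(same$delta_qaly, 0, tolerance = 1e-12)
  # lower CM hazard with equal utilities everywhere: CM accrues fewer
  # surgical episodes, so delta_cost < 0
  eq_u <- c(NoSurgery = 0.7, RecoveryTunnel = 0.7, SymptomsResolved = 0.7,
            SymptomsPersist = 0.7, Death = 0)
  cmp <- compare_strategies(
    markov_spec("LC", utilities = eq_u, life_table = lt),
    markov_spec("CM", utilities = eq_u, life_table = lt))
  expect_lt(cmp$delta_cost, 0)
  expect_equal(cmp$delta_qaly, 0, tolerance = 1e-10)
  # a deeper tunnel decrement widens the QALY gap in CM's favour
  deep <- function(u_rec) compare_strategies(
    markov_spec("LC", utilities = replace(eq_u, "RecoveryTunnel", u_rec),
                life_table = lt),
    markov_spec("CM", utilities = replace(eq_u, "RecoveryTunnel", u_rec),
                life_table = lt))
  expect_gt(deep(0.4)$delta_qaly, deep(0.6)$delta_qaly * 1.0)
  expect_gt(deep(0.4)$delta_qaly, 0)
  expect_error(compare_strategies(
    markov_spec("LC", horizon = 120), markov_spec("CM", horizon = 60)),
    "horizon")
})

test_that("equal resolved/persist utilities make p_resolved irrelevant to QALYs", {
  lt <- load_life_table()
  totals <- vapply(c(0.1, 0.5, 0.9), function(pr)
    run_cohort(markov_spec("LC", p_resolved = pr, life_table = lt))$total_qaly,
    numeric(1))
  expect_equal(totals[1], totals[2], tolerance = 1e-12)
  expect_equal(totals[2], totals[3], tolerance = 1e-12)
})

test_that("time-varying utility schedules override the first cycles only", {
  lt <- load_life_table()
  base <- markov_spec("LC", life_table = lt)
  sched <- matrix(rep(unname(base$utilities[c("NoSurgery", "RecoveryTunnel",
                                              "SymptomsResolved",
                                              "SymptomsPersist", "Death")]),
                      each = 48),
                  nrow = 48,
                  dimnames = list(NULL, c("NoSurgery", "RecoveryTunnel",
                                          "SymptomsResolved",
                                          "SymptomsPersist", "Death")))
  same <- markov_spec("LC", utility_schedule = sched, life_table = lt)
  expect_equal(run_cohort(same)$total_qaly, run_cohort(base)$total_qaly)
  lower <- sched
  lower[, "NoSurgery"] <- 0.5
  worse <- markov_spec("LC", utility_schedule = lower, life_table = lt)
  expect_lt(run_cohort(worse)$total_qaly, run_cohort(base)$total_qaly)
})

test_that("microsimulation is deterministic and degenerate without events", {
  spec <- markov_spec("LC", uptake = 0,
                      utilities = c(NoSurgery = 0.8, RecoveryTunnel = 0.8,
                                    SymptomsResolved = 0.8,
                                    SymptomsPersist = 0.8, Death = 0),
                      state_costs = c(NoSurgery = 10, RecoveryTunnel = 10,
                                      SymptomsResolved = 10,
                                      SymptomsPersist = 10, Death = 0),
                      surgery_episode_cost = 0,
                      life_table = zero_mortality_table())
  ms <- microsim_oracle(spec, 1000, seed = 3)
  tr <- run_cohort(spec)
  # no stochastic events: every individual accrues the cohort totals
  expect_equal(ms$mean_qaly, tr$total_qaly, tolerance = 1e-12)
  expect_equal(ms$mean_cost, tr$total_cost, tolerance = 1e-10)
  expect_equal(ms$se_qaly, 0)
  a <- microsim_oracle(markov_spec("CM"), 2000, seed = 5)
  b <- microsim_oracle(markov_spec("CM"), 2000, seed = 5)
  expect_identical(a, b)
  expect_error(microsim_oracle(spec, 10, seed = 1), "n_individuals")
})

test_that("PSA collapses under zero-variance distributions and is seeded", {
  lt <- load_life_table()
  sl <- markov_spec("LC", life_table = lt)
  sc <- markov_spec("CM", life_table = lt)
  degenerate <- psa_config(list(
    list(name = "p_resolved", dist = "beta", mean = 0.6, se = 0),
    list(name = "surgery_episode_cost", dist = "gamma", mean = 2900, se = 0)
  ), n_draws = 100, seed = 4)
  res <- run_psa(sl, sc, degenerate)
  expect_equal(unique(res$draws$delta_cost), res$deterministic$delta_cost)
  expect_equal(unique(res$draws$delta_qaly), res$deterministic$delta_qaly)
  varied <- psa_config(list(
    list(name = "p_resolved", dist = "beta", mean = 0.6, se = 0.1),
    list(name = "utility:RecoveryTunnel", dist = "beta_utility",
         mean = 0.6, se = 0.05),
    list(name = "hazard_scale", dist = "gamma", mean = 1, se = 0.05,
         strategy = "CM")
  ), n_draws = 120, seed = 9)
  r1 <- run_psa(sl, sc, varied)
  r2 <- run_psa(sl, sc, varied)
  expect_identical(r1$draws, r2$draws)
  expect_true(all(r1$ceac$probability >= 0 & r1$ceac$probability <= 1))
  expect_error(psa_config(list(list(name = "p_resolved", dist = "beta",
                                    mean = 1.2, se = 0.1))),
               "beta mean")
  expect_error(psa_config(list(list(name = "p_resolved", dist = "weird",
                                    mean = 0.5, se = 0.1))),
               "unknown distribution")
})
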