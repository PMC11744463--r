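# Within-trial CUA machinery: imputation, adjusted models, Rubin
# pooling, bootstrap, ICER, CEAC.

test_that("Rubin pooling reproduces hand computations", {
  # zero between-imputation variance: pooled = the common estimate
  p <- pool_rubin(rep(1.7, 5), rep(0.4, 5))
  expect_equal(p$delta, 1.7)
  expect_equal(p$se, 0.4)
  # deltas {0, 2} with zero within-variance: var = (1 + 1/2) * 2 = 3
  p2 <- pool_rubin(c(0, 2), c(0, 0))
  expect_equal(p2$delta, 1)
  expect_equal(p2$se^2, 3)
  # total variance never below the mean within-variance
  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(5)
    s <- runif(5, 0.1, 2)
    expect_gte(pool_rubin(d, s)$se^2, mean(s^2))
  }
  expect_error(pool_rubin(1, 1), "m >= 2")
})

test_that("ICER sign logic and undefined flagging behave", {
  x <- compute_icer(-1003, -0.068)
  expect_equal(x$icer, 14750, tolerance = 1 / 14750)
  expect_equal(x$quadrant, "SW")
  d <- compute_icer(-100, 0.1)
  expect_equal(d$quadrant, "dominant")
  expect_equal(d$icer, -1000)
  expect_equal(compute_icer(0, 0.1)$icer, 0)
  expect_equal(compute_icer(100, -0.1)$quadrant, "dominated")
  expect_equal(compute_icer(100, 0.1)$quadrant, "NE")
  z <- compute_icer(5, 0)
  expect_false(z$defined)
  expect_true(is.na(z$icer))
})

test_that("CEAC probabilities follow the net-benefit rule", {
  lambdas <- c(0, 13000, 20000, 30000)
  # pure saving: probability 1 everywhere
  one <- data.frame(delta_cost = -10, delta_qaly = 0)
  expect_equal(ceac_curve(one, lambdas)$probability, rep(1, 4))
  # draws symmetric around the origin: probability one half
  sym <- data.frame(delta_cost = c(-5, 5, -2, 2),
                    delta_qaly = c(-0.1, 0.1, 0.2, -0.2))
  expect_equal(ceac_curve(sym, lambdas)$probability, rep(0.5, 4))
  # at lambda = 0 the CEAC equals the fraction of cost-saving draws
  set.seed(42)
  cloud <- data.frame(delta_cost = rnorm(500, -200, 400),
                      delta_qaly = rnorm(500, 0, 0.05))
  expect_equal(ceac_curve(cloud, 0)$probability,
               mean(cloud$delta_cost < 0))
  # orientation flip complements the probability (no ties here)
  p_cm <- ceac_curve(cloud, 20000)$probability
  p_lc <- ceac_curve(cloud, 20000, orientation = "LC_vs_CM")$probability
  expect_equal(p_cm + p_lc, 1)
  expect_error(ceac_curve(cloud[0, ], 0), "draws")
})

test_that("INB is affine in the threshold with slope delta_qaly", {
  inb <- inb_curve(-1033, -0.019, c(0, 13000, 20000, 30000))
  expect_equal(inb$inb, c(0, 13000, 20000, 30000) * -0.019 + 1033)
  expect_equal(diff(inb$inb) / diff(inb$threshold), rep(-0.019, 3))
})

test_that("imputation is proper, deterministic, and the identity when complete", {
  coh <- generate_cohort(small_params(seed = 6))
  # nothing to impute: m identical copies of the input
  imps <- impute_missing(coh, m = 3, seed = 1)
  expect_length(imps, 3)
  for (d in imps) expect_identical(d, coh)
  # with missingness: completed, in range, deterministic given seed
  mis <- apply_missingness(coh, "MAR", 0.25, seed = 2)
  a <- impute_missing(mis, m = 4, seed = 11)
  b <- impute_missing(mis, m = 4, seed = 11)
  expect_identical(a, b)
  for (d in a) {
    um <- as.matrix(d[grep("^util_", names(d))])
    expect_false(anyNA(um))
    expect_true(all(um >= -0.59 & um <= 1))
  }
  # observed entries are untouched; different imputations differ
  obs <- !is.na(mis$util_24)
  expect_equal(a[[1]]$util_24[obs], mis$util_24[obs])
  expect_false(identical(a[[1]]$util_24, a[[2]]$util_24))
  expect_error(impute_missing(mis, m = 1, seed = 1), "m")
  # a column with no observed values cannot be imputed
  broken <- mis
  broken$util_24 <- NA_real_
  expect_error(impute_missing(broken, m = 2, seed = 1), "util_24")
})

test_that("adjusted incrementals are zero under identical outcomes and track raw differences", {
  coh <- generate_cohort(small_params(seed = 8))
  n <- nrow(coh)
  const_cost <- rep(1500, n)
  const_qaly <- rep(1.4, n)
  fit <- adjusted_incrementals(coh, const_cost, const_qaly)
  expect_equal(fit$delta_cost, 0, tolerance = 1e-8)
  expect_equal(fit$delta_qaly, 0, tolerance = 1e-10)
  # covariate-balanced large n: adjusted estimate close to raw difference
  big <- generate_cohort(trial_params(n_per_arm = 2000L, seed = 12))
  costs <- fixture_costs()
  cst <- cohort_costs(big, costs)
  q <- cohort_qalys(big)
  fit2 <- adjusted_incrementals(big, cst, q)
  lc <- big$arm == "LC"
  raw_c <- mean(cst[!lc]) - mean(cst[lc])
  raw_q <- mean(q[!lc]) - mean(q[lc])
  expect_lt(abs(fit2$delta_cost - raw_c), 3 * fit2$se_cost)
  expect_lt(abs(fit2$delta_qaly - raw_q), 3 * fit2$se_qaly)
})

test_that("singleton centres are pooled with a warning", {
  coh <- generate_cohort(small_params(seed = 10))
  coh$centre[1] <- 99L
  expect_warning(
    adjusted_incrementals(coh, rep(1, nrow(coh)) + coh$age / 100,
                          rep(1, nrow(coh))),
    "single participant")
})

test_that("bootstrap draws are joint, deterministic, and degenerate when data are", {
  coh <- generate_cohort(small_params(seed = 14))
  costs <- fixture_costs()
  mis <- apply_missingness(coh, "MAR", 0.15, seed = 3)
  d1 <- bootstrap_joint(mis, costs, B = 100, seed = 21)
  d2 <- bootstrap_joint(mis, costs, B = 100, seed = 21)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 100)
  expect_false(anyNA(d1$delta_cost))
  expect_error(bootstrap_joint(mis, costs, B = 50, seed = 1), "B")
  # degenerate outcomes: every draw identical (no missingness, constant
  # utilities and resources)
  flat <- coh
  for (cn in grep("^util_", names(flat), value = TRUE)) flat[[cn]] <- 0.7
  flat$had_surgery <- FALSE
  flat$surgery_month <- NA_real_
  flat$theatre_minutes <- 0
  flat$stay_days <- 0
  flat$readmissions <- 1L
  flat$ae_attendances <- 1L
  flat$primary_care_visits <- 2L
  dd <- bootstrap_joint(flat, costs, B = 100, seed = 5)
  expect_equal(diff(range(dd$delta_cost)), 0, tolerance = 1e-6)
  expect_equal(diff(range(dd$delta_qaly)), 0, tolerance = 1e-9)
})

test_that("the full pipeline on complete data collapses to the single fit", {
  coh <- generate_cohort(small_params(seed = 16))
  costs <- fixture_costs()
  res <- within_trial_cea(coh, costs, m = 3, B = 100, seed = 2)
  direct <- adjusted_incrementals(coh, cohort_costs(coh, costs),
                                  cohort_qalys(coh))
  # m identical completed copies: pooled point equals the direct fit
  expect_equal(res$delta_cost, direct$delta_cost)
  expect_equal(res$delta_qaly, direct$delta_qaly)
  expect_equal(res$se_cost, direct$se_cost)
  # interval brackets the point; CEAC probabilities in [0, 1]
  expect_lte(res$ci_cost[1], res$delta_cost)
  expect_gte(res$ci_cost[2], res$delta_cost)
  expect_true(all(res$ceac$probability >= 0 & res$ceac$probability <= 1))
  # INB identity at the configured thresholds
  expect_equal(res$inb$inb,
               res$ceac$threshold * res$delta_qaly - res$delta_cost)
})
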