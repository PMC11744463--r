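# Within-trial cost-utility analysis at 24 months: adjusted incremental
# costs and QALYs (GLM, minimization factors centre/age/sex plus
# baseline utility), chained-equations multiple imputation, stratified
# non-parametric bootstrap, ICER, CEAC and net monetary benefit.
# Orientation throughout: CM minus LC.

#' @noRd
pool_singleton_centres <- function(data, quiet = FALSE) {
  tab <- table(data$centre)
  singles <- names(tab)[tab == 1L]
  if (length(singles)) {
    ref <- names(tab)[which.max(tab)]
    if (!quiet) {
      warning(sprintf(
        "centre(s) %s have a single participant; pooled into centre %s",
        paste(singles, collapse = ", "), ref), call. = FALSE)
    }
    data$centre[as.character(data$centre) %in% singles] <- type.convert(
      ref, as.is = TRUE)
  }
  data
}

#' Design matrix for the adjustment model
#'
#' arm (LC reference) + centre fixed effects + age + sex + baseline
#' utility. Returns the matrix and the arm-dummy column index.
#' @noRd
cua_design <- function(data) {
  arm <- factor(data$arm, levels = c("LC", "CM"))
  centre <- factor(data$centre)
  X <- stats::model.matrix(~ arm + centre + age + sex + baseline_utility,
                           data.frame(arm = arm, centre = centre,
                                      age = data$age, sex = factor(data$sex),
                                      baseline_utility = data$baseline_utility))
  list(X = X, arm_col = match("armCM", colnames(X)))
}

#' Linear-model arm effect with (optionally robust) standard error
#'
#' With `robust = TRUE` the s.e. is the HC1 heteroscedasticity-robust
#' sandwich, appropriate for right-skewed, bimodal cost residuals.
#' @noRd
lm_delta <- function(X, y, arm_col, robust = FALSE) {
  fit <- stats::lm.fit(X, y)
  ok <- !is.na(fit$coefficients)
  if (!ok[arm_col]) stop("arm effect not estimable", call. = FALSE)
  Xok <- X[, ok, drop = FALSE]
  XtXinv <- chol2inv(chol(crossprod(Xok)))
  n <- nrow(X)
  p <- sum(ok)
  j <- sum(ok[seq_len(arm_col)])
  if (robust) {
    meat <- crossprod(Xok * fit$residuals^2, Xok)
    V <- XtXinv %*% meat %*% XtXinv * n / (n - p)
    se <- sqrt(V[j, j])
  } else {
    sigma2 <- sum(fit$residuals^2) / (n - p)
    se <- sqrt(sigma2 * XtXinv[j, j])
  }
  list(delta = unname(fit$coefficients[arm_col]), se = se)
}

#' Adjusted incremental cost and QALY from one completed dataset
#'
#' Regresses per-participant total cost and total QALY on the arm
#' indicator plus the minimization factors (centre as fixed effects,
#' age, sex) and baseline utility. Both are identity-link generalised
#' linear models, so the arm coefficient is the incremental in natural
#' units (GBP, QALYs). The cost model carries an HC1
#' heteroscedasticity-robust standard error, since trial costs are
#' right-skewed with a point mass from unoperated participants; an
#' identity link keeps the adjusted arm contrast unbiased for additive
#' cost structures and is defined at zero cost (a log-link gamma
#' marginal contrast is neither). Centres with a single participant
#' are pooled into the largest centre with a warning.
#'
#' @param data a completed (no missing utilities) `participant_data`
#'   data frame.
#' @param cost per-participant discounted total costs (GBP), as from
#'   [cohort_costs()].
#' @param qaly per-participant discounted QALYs, as from
#'   [cohort_qalys()].
#' @return A list of class `incremental_fit`: `delta_cost`, `se_cost`,
#'   `delta_qaly`, `se_qaly` (CM minus LC) and `cost_model`
#'   ("linear-hc1").
#' @export
adjusted_incrementals <- function(data, cost, qaly) {
  stopifnot(length(cost) == nrow(data), length(qaly) == nrow(data))
  data <- pool_singleton_centres(data)
  des <- cua_design(data)
  q <- lm_delta(des$X, qaly, des$arm_col)
  cfit <- lm_delta(des$X, cost, des$arm_col, robust = TRUE)
  structure(list(delta_cost = cfit$delta, se_cost = cfit$se,
                 delta_qaly = q$delta, se_qaly = q$se,
                 cost_model = "linear-hc1"),
            class = "incremental_fit")
}

#' Multiple imputation of missing utility visits by chained equations
#'
#' Fills missing post-baseline utility values with a
#' chained-equations scheme using Bayesian linear-regression draws:
#' for each visit column with missingness, a normal linear model on
#' arm, centre (fixed effects), age, sex, baseline utility and the
#' other visit columns is fitted to the observed rows; the residual
#' variance and coefficients are drawn from their posterior and
#' missing entries are imputed with posterior-predictive noise
#' (proper imputation), then clamped to the SF-6D range. Chains are
#' re-initialised per imputation, so the `m` completed datasets are
#' independent given the seed.
#'
#' @param data a `participant_data` data frame (missingness only in
#'   post-baseline utility columns).
#' @param m number of imputations (>= 2; use [single_impute()] inside
#'   resampling loops).
#' @param seed integer RNG seed.
#' @param maxit chained-equation sweeps per imputation.
#' @return A list of `m` completed data frames, class `imputed_sets`.
#' @export
impute_missing <- function(data, m = 20L, seed, maxit = 5L) {
  check_that(m >= 2, "m", "must be >= 2")
  with_seed(seed, {
    out <- lapply(seq_len(m), function(i) impute_once(data, maxit))
    structure(out, class = "imputed_sets", seed = seed, m = m)
  })
}

#' One stochastic completion of a dataset (for bootstrap resamples)
#'
#' Runs a single chained-equations imputation using the current RNG
#' stream (seed management is the caller's responsibility).
#' @inheritParams impute_missing
#' @return A completed data frame.
#' @export
single_impute <- function(data, maxit = 5L) {
  impute_once(data, maxit)
}

#' @noRd
impute_once <- function(data, maxit) {
  ucols <- grep("^util_", names(data), value = TRUE)
  post <- setdiff(ucols, "util_0")
  miss <- lapply(post, function(cn) which(is.na(data[[cn]])))
  names(miss) <- post
  targets <- post[vapply(miss, length, 1L) > 0L]
  if (!length(targets)) return(data)
  for (cn in targets) {
    if (all(is.na(data[[cn]]))) {
      stop("column '", cn, "' has no observed values; cannot impute",
           call. = FALSE)
    }
  }
  other_na <- setdiff(names(data)[vapply(data, anyNA, TRUE)],
                      c(post, "surgery_month"))
  if (length(other_na)) {
    stop("missingness outside post-baseline utilities: ",
         paste(other_na, collapse = ", "), call. = FALSE)
  }
  Xs <- cua_design(data)$X
  # initialise by sampling observed values within each column
  for (cn in targets) {
    obs <- data[[cn]][!is.na(data[[cn]])]
    data[[cn]][miss[[cn]]] <- sample(obs, length(miss[[cn]]), replace = TRUE)
  }
  for (it in seq_len(maxit)) {
    for (cn in targets) {
      mi <- miss[[cn]]
      X <- cbind(Xs, as.matrix(data[setdiff(post, cn)]))
      data[[cn]][mi] <- bayes_lm_draw(X[-mi, , drop = FALSE],
                                      data[[cn]][-mi],
                                      X[mi, , drop = FALSE])
    }
  }
  data
}

#' Posterior-predictive draw from a Bayesian linear regression
#' @noRd
bayes_lm_draw <- function(Xobs, yobs, Xmis) {
  p <- ncol(Xobs)
  XtX <- crossprod(Xobs) + diag(1e-8, p)
  ch <- chol(XtX)
  bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(Xobs, yobs)))
  rss <- sum((yobs - Xobs %*% bhat)^2)
  df <- max(nrow(Xobs) - p, 1)
  sigma2 <- rss / stats::rchisq(1, df)
  beta <- bhat + sqrt(sigma2) * backsolve(ch, stats::rnorm(p))
  y <- as.numeric(Xmis %*% beta) + stats::rnorm(nrow(Xmis), 0, sqrt(sigma2))
  pmin(pmax(y, UTILITY_FLOOR), UTILITY_CEIL)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point = mean of the per-imputation estimates; total variance
#' = mean within-imputation variance + (1 + 1/m) times the
#' between-imputation variance.
#'
#' @param deltas per-imputation point estimates.
#' @param ses per-imputation standard errors.
#' @return List with `delta` (pooled point) and `se` (sqrt of total
#'   variance).
#' @export
pool_rubin <- function(deltas, ses) {
  m <- length(deltas)
  check_that(m >= 2 && length(ses) == m, "deltas/ses",
             "need m >= 2 paired estimates")
  W <- mean(ses^2)
  B <- stats::var(deltas)
  list(delta = mean(deltas), se = sqrt(W + (1 + 1 / m) * B))
}

#' Joint bootstrap of incremental cost and QALY
#'
#' Resamples participants with replacement, stratified by arm; within
#' each resample performs one stochastic imputation of missing
#' utilities, recomputes discounted costs and QALYs, and refits the
#' adjusted models. The draws preserve the joint distribution of
#' (delta_cost, delta_qaly). Resamples where a model fails to fit are
#' redrawn; more than 1% redraws is an error.
#'
#' @param data a `participant_data` data frame (may contain missing
#'   utilities).
#' @param costs a [unit_cost_table()].
#' @param B number of bootstrap draws (>= 100).
#' @param seed integer RNG seed.
#' @param rate annual discount rate.
#' @param maxit chained-equation sweeps per resample imputation.
#' @return Data frame of class `bootstrap_draws` with columns
#'   `delta_cost`, `delta_qaly`; attributes `seed`, `scheme`,
#'   `n_redraws`.
#' @export
bootstrap_joint <- function(data, costs, B = 1000L, seed, rate = 0.035,
                            maxit = 5L) {
  check_that(B >= 100, "B", "must be >= 100")
  validate_unit_costs(costs)
  followup <- max(as.numeric(sub("^util_", "",
                                 grep("^util_", names(data), value = TRUE))))
  idx_arm <- split(seq_len(nrow(data)), data$arm)
  max_redraws <- max(1, ceiling(0.01 * B))
  with_seed(seed, {
    dc <- dq <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- unlist(lapply(idx_arm, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
        res <- tryCatch({
          d <- data[idx, , drop = FALSE]
          d <- single_impute(d, maxit)
          suppressWarnings(adjusted_incrementals(
            d, cohort_costs(d, costs, rate, followup),
            cohort_qalys(d, rate)))
        }, error = function(e) NULL)
        if (!is.null(res)) break
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop("more than 1% of bootstrap resamples failed to fit",
               call. = FALSE)
        }
      }
      dc[b] <- res$delta_cost
      dq[b] <- res$delta_qaly
    }
    structure(data.frame(delta_cost = dc, delta_qaly = dq),
              class = c("bootstrap_draws", "data.frame"),
              seed = seed,
              scheme = "stratified-by-arm, impute-within-resample",
              n_redraws = redraws)
  })
}

#' Incremental cost-effectiveness ratio with quadrant label
#'
#' The quadrant comes from the signs of the incrementals (CM minus
#' LC): `dominant` (cheaper, more effective), `dominated` (dearer,
#' less effective), `NE` (dearer, more effective), `SW` (cheaper, less
#' effective -- the ratio is savings per QALY forgone). When
#' `delta_qaly` is zero the ratio is undefined and flagged rather than
#' thrown.
#'
#' @param delta_cost incremental cost (GBP).
#' @param delta_qaly incremental QALYs.
#' @return List of class `icer`: `icer`, `quadrant`, `defined`.
#' @examples
#' compute_icer(-1003, -0.068)  # ~14750 GBP saved per QALY forgone (SW)
#' @export
compute_icer <- function(delta_cost, delta_qaly) {
  quadrant <- if (delta_cost == 0 && delta_qaly == 0) "indifferent"
  else if (delta_qaly > 0 && delta_cost <= 0) "dominant"
  else if (delta_qaly < 0 && delta_cost >= 0) "dominated"
  else if (delta_cost > 0) "NE"
  else "SW"
  defined <- delta_qaly != 0
  structure(list(
    icer = if (defined) delta_cost / delta_qaly else NA_real_,
    quadrant = quadrant,
    defined = defined
  ), class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("ICER: %.0f GBP/QALY [%s]\n", x$icer, x$quadrant))
  } else {
    cat(sprintf("ICER undefined (zero incremental QALYs) [%s]\n", x$quadrant))
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the comparator (CM by default) is cost-effective
#' at each willingness-to-pay threshold: the fraction of joint draws
#' with positive incremental net benefit
#' \eqn{\lambda \Delta QALY - \Delta Cost > 0}; exact ties count 0.5.
#'
#' @param draws a `bootstrap_draws` data frame (CM-minus-LC deltas).
#' @param thresholds willingness-to-pay values (GBP/QALY, >= 0).
#' @param orientation `"CM_vs_LC"` (use draws as-is) or `"LC_vs_CM"`
#'   (negate them).
#' @return Data frame with columns `threshold`, `probability`.
#' @export
ceac_curve <- function(draws, thresholds = c(13000, 20000, 30000),
                       orientation = c("CM_vs_LC", "LC_vs_CM")) {
  orientation <- match.arg(orientation)
  if (nrow(draws) < 1) stop("no bootstrap draws", call. = FALSE)
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  s <- if (orientation == "CM_vs_LC") 1 else -1
  dc <- s * draws$delta_cost
  dq <- s * draws$delta_qaly
  prob <- vapply(thresholds, function(l) {
    nb <- l * dq - dc
    mean((nb > 0) + 0.5 * (nb == 0))
  }, numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Incremental net monetary benefit at given thresholds
#'
#' @param delta_cost,delta_qaly pooled incrementals (CM minus LC).
#' @param thresholds willingness-to-pay values (GBP/QALY).
#' @return Data frame with columns `threshold`, `inb` where
#'   `inb = threshold * delta_qaly - delta_cost`.
#' @export
inb_curve <- function(delta_cost, delta_qaly,
                      thresholds = c(13000, 20000, 30000)) {
  data.frame(threshold = thresholds,
             inb = thresholds * delta_qaly - delta_cost)
}

#' Within-trial cost-utility analysis
#'
#' Full pipeline: multiple imputation (`m` completed datasets) for the
#' pooled point estimates via Rubin's rules; stratified bootstrap with
#' within-resample imputation for joint uncertainty; percentile
#' intervals; ICER with quadrant; CEAC and INB at the configured
#' thresholds.
#'
#' @inheritParams bootstrap_joint
#' @param m number of imputations for the point estimate.
#' @param thresholds willingness-to-pay thresholds (GBP/QALY).
#' @param discount_rate annual discount rate.
#' @return An object of class `cea_result`.
#' @export
within_trial_cea <- function(data, costs, m = 20L, B = 1000L, seed = 1L,
                             thresholds = c(13000, 20000, 30000),
                             discount_rate = 0.035) {
  validate_unit_costs(costs)
  followup <- max(as.numeric(sub("^util_", "",
                                 grep("^util_", names(data), value = TRUE))))
  imps <- impute_missing(data, m = m, seed = seed)
  fits <- lapply(imps, function(d) {
    suppressWarnings(adjusted_incrementals(
      d, cohort_costs(d, costs, discount_rate, followup),
      cohort_qalys(d, discount_rate)))
  })
  pc <- pool_rubin(vapply(fits, `[[`, 1, "delta_cost"),
                   vapply(fits, `[[`, 1, "se_cost"))
  pq <- pool_rubin(vapply(fits, `[[`, 1, "delta_qaly"),
                   vapply(fits, `[[`, 1, "se_qaly"))
  draws <- bootstrap_joint(data, costs, B = B, seed = seed + 1L,
                           rate = discount_rate)
  ci_cost <- stats::quantile(draws$delta_cost, c(0.025, 0.975), names = FALSE)
  ci_qaly <- stats::quantile(draws$delta_qaly, c(0.025, 0.975), names = FALSE)
  structure(list(
    delta_cost = pc$delta, se_cost = pc$se, ci_cost = ci_cost,
    delta_qaly = pq$delta, se_qaly = pq$se, ci_qaly = ci_qaly,
    icer = compute_icer(pc$delta, pq$delta),
    ceac = ceac_curve(draws, thresholds),
    inb = inb_curve(pc$delta, pq$delta, thresholds),
    draws = draws,
    n_bootstrap = nrow(draws), n_imputations = length(imps),
    seed = seed, discount_rate = discount_rate
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Within-trial cost-utility analysis (CM minus LC)\n")
  cat(sprintf("  incremental cost: %.0f GBP (95%% CI %.0f, %.0f)\n",
              x$delta_cost, x$ci_cost[1], x$ci_cost[2]))
  cat(sprintf("  incremental QALY: %.4f (95%% CI %.4f, %.4f)\n",
              x$delta_qaly, x$ci_qaly[1], x$ci_qaly[2]))
  print(x$icer)
  cat(sprintf("  imputations m = %d, bootstrap B = %d\n",
              x$n_imputations, x$n_bootstrap))
  cat("  probability CM cost-effective:\n")
  for (i in seq_len(nrow(x$ceac))) {
    cat(sprintf("    at %6.0f GBP/QALY: %.3f\n",
                x$ceac$threshold[i], x$ceac$probability[i]))
  }
  invisible(x)
}
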