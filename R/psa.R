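# Probabilistic sensitivity analysis for the Markov model: parameter
# distributions (beta for probabilities, gamma for costs, beta on the
# rescaled SF-6D support for utilities), method-of-moments fitted from
# mean and s.e.

#' PSA configuration
#'
#' Each element of `params` is a list with fields:
#' \describe{
#'   \item{name}{addressable parameter: `"p_resolved"`,
#'     `"surgery_episode_cost"`, `"hazard_scale"` (multiplies the
#'     surgery schedule), `"utility:<State>"` or `"cost:<State>"`.}
#'   \item{dist}{`"beta"`, `"gamma"`, `"beta_utility"` (beta rescaled
#'     to \eqn{[-0.59, 1]}) or `"fixed"`.}
#'   \item{mean, se}{moments on the natural scale; `se = 0` collapses
#'     to the mean.}
#'   \item{strategy}{`"both"` (default, one shared draw applied to both
#'     strategies), `"LC"` or `"CM"`.}
#' }
#'
#' @param params list of parameter specs (see details).
#' @param n_draws number of Monte-Carlo draws (>= 100).
#' @param seed integer RNG seed.
#' @return A validated list of class `psa_config`.
#' @export
psa_config <- function(params, n_draws = 1000L, seed = 1L) {
  check_that(n_draws >= 100, "n_draws", "must be >= 100")
  for (p in params) {
    check_that(!is.null(p$name) && !is.null(p$dist) && !is.null(p$mean),
               "params", "each entry needs name, dist and mean")
    se <- if (is.null(p$se)) 0 else p$se
    check_that(se >= 0, p$name, "se must be >= 0")
    if (p$dist == "beta") {
      check_that(p$mean > 0 && p$mean < 1, p$name,
                 "beta mean must lie in (0, 1)")
      check_that(se^2 < p$mean * (1 - p$mean), p$name,
                 "beta variance must be < mean*(1-mean)")
    } else if (p$dist == "beta_utility") {
      m <- (p$mean - UTILITY_FLOOR) / (1 - UTILITY_FLOOR)
      check_that(m > 0 && m < 1, p$name,
                 "utility mean must lie inside (-0.59, 1)")
      v <- se^2 / (1 - UTILITY_FLOOR)^2
      check_that(v < m * (1 - m), p$name, "utility variance too large")
    } else if (p$dist == "gamma") {
      check_that(p$mean > 0, p$name, "gamma mean must be > 0")
    } else if (p$dist != "fixed") {
      stop(sprintf("unknown distribution '%s' for parameter '%s'",
                   p$dist, p$name), call. = FALSE)
    }
  }
  structure(list(params = params, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)), class = "psa_config")
}

#' Method-of-moments sampler for one PSA parameter
#' @noRd
psa_sample <- function(p, n) {
  se <- if (is.null(p$se)) 0 else p$se
  if (p$dist == "fixed" || se == 0) return(rep(p$mean, n))
  switch(p$dist,
    beta = {
      m <- p$mean
      v <- se^2
      nu <- m * (1 - m) / v - 1
      stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    gamma = {
      shape <- (p$mean / se)^2
      stats::rgamma(n, shape = shape, rate = shape / p$mean)
    },
    beta_utility = {
      w <- 1 - UTILITY_FLOOR
      m <- (p$mean - UTILITY_FLOOR) / w
      v <- se^2 / w^2
      nu <- m * (1 - m) / v - 1
      UTILITY_FLOOR + w * stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    stop("unknown distribution: ", p$dist, call. = FALSE)
  )
}

#' @noRd
set_markov_param <- function(spec, name, value) {
  if (name == "p_resolved") {
    spec$p_resolved <- value
  } else if (name == "surgery_episode_cost") {
    spec$surgery_episode_cost <- value
  } else if (name == "hazard_scale") {
    spec$surgery_schedule <- pmin(spec$surgery_schedule * value, 1)
    spec$post24_hazard <- min(spec$post24_hazard * value, 1)
  } else if (startsWith(name, "utility:")) {
    state <- sub("^utility:", "", name)
    check_that(state %in% MARKOV_STATES, name, "unknown state")
    spec$utilities[[state]] <- value
  } else if (startsWith(name, "cost:")) {
    state <- sub("^cost:", "", name)
    check_that(state %in% MARKOV_STATES, name, "unknown state")
    spec$state_costs[[state]] <- value
  } else {
    stop(sprintf("unknown PSA parameter '%s'", name), call. = FALSE)
  }
  spec
}

#' Probabilistic sensitivity analysis of the Markov comparison
#'
#' Per draw, samples every uncertain parameter, applies the shared or
#' strategy-specific values to both specs, runs both cohorts and
#' records the joint CM-minus-LC incrementals. The CEAC is computed
#' exactly as in the within-trial analysis.
#'
#' @param spec_LC,spec_CM strategy [markov_spec()] objects.
#' @param psa a [psa_config()].
#' @param thresholds willingness-to-pay thresholds (GBP/QALY).
#' @return List of class `psa_result`: `draws` (a `bootstrap_draws`
#'   data frame), `ceac`, `deterministic` (the no-uncertainty
#'   comparison), `mean_delta_cost`, `mean_delta_qaly`.
#' @export
run_psa <- function(spec_LC, spec_CM, psa,
                    thresholds = c(13000, 20000, 30000)) {
  stopifnot(inherits(psa, "psa_config"))
  det <- compare_strategies(spec_LC, spec_CM)
  n <- psa$n_draws
  with_seed(psa$seed, {
    draws_mat <- lapply(psa$params, psa_sample, n = n)
    dc <- dq <- numeric(n)
    for (i in seq_len(n)) {
      sl <- spec_LC
      sc <- spec_CM
      for (j in seq_along(psa$params)) {
        p <- psa$params[[j]]
        v <- draws_mat[[j]][i]
        strat <- if (is.null(p$strategy)) "both" else p$strategy
        if (strat %in% c("both", "LC")) sl <- set_markov_param(sl, p$name, v)
        if (strat %in% c("both", "CM")) sc <- set_markov_param(sc, p$name, v)
      }
      cmp <- compare_strategies(sl, sc)
      dc[i] <- cmp$delta_cost
      dq[i] <- cmp$delta_qaly
    }
    draws <- structure(data.frame(delta_cost = dc, delta_qaly = dq),
                       class = c("bootstrap_draws", "data.frame"),
                       seed = psa$seed, scheme = "markov-psa")
    structure(list(
      draws = draws,
      ceac = ceac_curve(draws, thresholds),
      deterministic = det,
      mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq)
    ), class = "psa_result")
  })
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Markov PSA, %d draws (CM minus LC)\n", nrow(x$draws)))
  cat(sprintf("  mean delta cost %+.2f GBP, mean delta QALY %+.4f\n",
              x$mean_delta_cost, x$mean_delta_qaly))
  cat("  probability CM cost-effective:\n")
  for (i in seq_len(nrow(x$ceac))) {
    cat(sprintf("    at %6.0f GBP/QALY: %.3f\n",
                x$ceac$threshold[i], x$ceac$probability[i]))
  }
  invisible(x)
}
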