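# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded package functions do not perturb the
#' user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# SF-6D instrument range: utilities live in [-0.59, 1].
UTILITY_FLOOR <- -0.59
UTILITY_CEIL <- 1

#' Truncated-normal sampler (inverse-CDF method, vectorised)
#' @noRd
rtnorm <- function(n, mean, sd, lower = UTILITY_FLOOR, upper = UTILITY_CEIL) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n)
  x <- stats::qnorm(pl + u * (pu - pl), mean, sd)
  # guard against numerically exact tail quantiles
  pmin(pmax(x, lower), upper)
}

#' Mean of a truncated normal distribution (closed form)
#' @noRd
etnorm <- function(mean, sd, lower = UTILITY_FLOOR, upper = UTILITY_CEIL) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Calendar year (1-based) containing a trial month
#'
#' Months in (0, 12] fall in year 1, (12, 24] in year 2, and so on;
#' month 0 is year 1.
#' @noRd
year_of_month <- function(month) {
  pmax(1, ceiling(month / 12))
}

#' Stop with a parameter error naming the offending field
#' @noRd
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

#' md5 hash of an R object via its YAML serialisation
#' @noRd
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}
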