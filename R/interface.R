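# Pipeline commands tying the modules together: simulate a trial
# dataset, run the within-trial analysis, run the decision model.
# Configuration is YAML (or an equivalent R list); every stochastic
# command requires an explicit seed. Results go to files; a
# run_log.json sidecar records the seed, the config hash and the md5
# of every artifact (audit trail).

#' Read a run configuration
#'
#' @param config a YAML file path or a named list.
#' @return The configuration as a list.
#' @export
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  config
}

#' @noRd
require_seed <- function(block, where) {
  if (is.null(block$seed)) {
    stop(sprintf(
      "config block '%s' has no 'seed'; stochastic commands require an explicit seed",
      where), call. = FALSE)
  }
  as.integer(block$seed)
}

#' @noRd
write_run_log <- function(out_dir, command, seed, config, files) {
  log <- list(
    command = command,
    seed = seed,
    config_md5 = config_hash(config),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  path <- file.path(out_dir, paste0("run_log_", command, ".json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' @noRd
audit_block <- function(seed, config) {
  list(seed = seed, config_md5 = config_hash(config))
}

#' Simulate a trial dataset to disk
#'
#' Writes the complete cohort CSV, the missingness-applied CSV and the
#' generator's closed-form truth summary (JSON), plus a run log with
#' the seed and config hash.
#'
#' @param config YAML path or list with a `generator` block
#'   ([trial_params()] fields; `seed` mandatory) and optional
#'   `missingness` block (`mechanism`, `rate`, `seed`).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of written file paths.
#' @export
cmd_simulate <- function(config, out_dir) {
  config <- read_config(config)
  gen <- config$generator
  if (is.null(gen)) stop("config lacks a 'generator' block", call. = FALSE)
  seed <- require_seed(gen, "generator")
  params <- do.call(trial_params, gen)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(params)
  mb <- config$missingness
  mechanism <- if (is.null(mb$mechanism)) "MAR" else mb$mechanism
  rate <- if (is.null(mb$rate)) params$missing_rate else mb$rate
  mseed <- if (is.null(mb$seed)) seed + 1L else as.integer(mb$seed)
  masked <- apply_missingness(cohort, mechanism, rate, mseed)
  truth <- truth_summary(params)

  f_full <- file.path(out_dir, "cohort.csv")
  f_miss <- file.path(out_dir, "cohort_missing.csv")
  f_truth <- file.path(out_dir, "truth.json")
  write_participant_csv(cohort, f_full)
  write_participant_csv(masked, f_miss)
  jsonlite::write_json(
    c(unclass(truth), list(audit = audit_block(seed, config))),
    f_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_log(out_dir, "simulate", seed, config,
                c(f_full, f_miss, f_truth))
  invisible(list(cohort = f_full, cohort_missing = f_miss, truth = f_truth))
}

#' Run the within-trial cost-utility analysis to disk
#'
#' Executes costing, multiple imputation, bootstrap, ICER, CEAC and
#' INB on a participant CSV; writes `cea_result.json` and a flat
#' `bootstrap_draws.csv` for cost-effectiveness-plane plotting.
#'
#' @param config YAML path or list with a `within_trial` block:
#'   `seed` (mandatory), optional `m`, `B`, `thresholds`,
#'   `discount_rate`, `unit_costs` (path or fixture name).
#' @param dataset path to a participant CSV
#'   ([write_participant_csv()] dialect).
#' @param out_dir output directory.
#' @return Invisibly, the `cea_result` object.
#' @export
cmd_within_trial <- function(config, dataset, out_dir) {
  config <- read_config(config)
  wt <- config$within_trial
  if (is.null(wt)) stop("config lacks a 'within_trial' block", call. = FALSE)
  seed <- require_seed(wt, "within_trial")
  data <- read_participant_csv(dataset)
  costs <- load_unit_costs(
    if (is.null(wt$unit_costs)) "unit_costs_synthetic" else wt$unit_costs)
  res <- within_trial_cea(
    data, costs,
    m = if (is.null(wt$m)) 20L else as.integer(wt$m),
    B = if (is.null(wt$B)) 1000L else as.integer(wt$B),
    seed = seed,
    thresholds = if (is.null(wt$thresholds)) c(13000, 20000, 30000)
    else as.numeric(wt$thresholds),
    discount_rate = if (is.null(wt$discount_rate)) 0.035
    else wt$discount_rate)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_json <- file.path(out_dir, "cea_result.json")
  f_draws <- file.path(out_dir, "bootstrap_draws.csv")
  report <- list(
    delta_cost = res$delta_cost, ci_cost = res$ci_cost,
    delta_qaly = res$delta_qaly, ci_qaly = res$ci_qaly,
    icer = res$icer$icer, icer_quadrant = res$icer$quadrant,
    ceac = res$ceac, inb = res$inb,
    n_bootstrap = res$n_bootstrap, n_imputations = res$n_imputations,
    audit = audit_block(seed, config)
  )
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  utils::write.csv(as.data.frame(res$draws), f_draws, row.names = FALSE)
  write_run_log(out_dir, "within_trial", seed, config, c(f_json, f_draws))
  invisible(res)
}

#' @noRd
spec_from_config <- function(block, strategy, life_table) {
  args <- block[setdiff(names(block), c("psa", "seed"))]
  for (nm in c("utilities", "state_costs")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  args$strategy <- strategy
  args$life_table <- life_table
  do.call(markov_spec, args)
}

#' Run the Markov model (deterministic + PSA) to disk
#'
#' Writes per-strategy cohort traces (`trace_LC.csv`, `trace_CM.csv`),
#' the deterministic comparison (`model_result.json`) and, when a
#' `psa` block is present, PSA draws (`psa_draws.csv`) with the PSA
#' CEAC folded into the JSON report.
#'
#' @param config YAML path or list with a `model` block: `seed`
#'   (mandatory), shared [markov_spec()] fields, optional `LC` / `CM`
#'   sub-blocks of strategy-specific overrides, optional `life_table`
#'   (path or fixture name), optional `thresholds`, and an optional
#'   `psa` block (`params` list, `n_draws`).
#' @param out_dir output directory.
#' @return Invisibly, a list with the deterministic comparison and the
#'   `psa_result` (or `NULL`).
#' @export
cmd_model <- function(config, out_dir) {
  config <- read_config(config)
  mb <- config$model
  if (is.null(mb)) stop("config lacks a 'model' block", call. = FALSE)
  seed <- require_seed(mb, "model")
  lt <- load_life_table(
    if (is.null(mb$life_table)) "life_table_synthetic" else mb$life_table)
  thresholds <- if (is.null(mb$thresholds)) c(13000, 20000, 30000)
  else as.numeric(mb$thresholds)
  shared <- mb[setdiff(names(mb),
                       c("LC", "CM", "psa", "seed", "life_table",
                         "thresholds"))]
  spec_lc <- spec_from_config(utils::modifyList(shared, as.list(mb$LC)),
                              "LC", lt)
  spec_cm <- spec_from_config(utils::modifyList(shared, as.list(mb$CM)),
                              "CM", lt)
  det <- compare_strategies(spec_lc, spec_cm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_lc <- file.path(out_dir, "trace_LC.csv")
  f_cm <- file.path(out_dir, "trace_CM.csv")
  write_trace_csv(det$LC, f_lc)
  write_trace_csv(det$CM, f_cm)
  files <- c(f_lc, f_cm)

  psa_res <- NULL
  if (!is.null(mb$psa)) {
    pc <- psa_config(mb$psa$params,
                     n_draws = if (is.null(mb$psa$n_draws)) 1000L
                     else as.integer(mb$psa$n_draws),
                     seed = seed)
    psa_res <- run_psa(spec_lc, spec_cm, pc, thresholds)
    f_psa <- file.path(out_dir, "psa_draws.csv")
    utils::write.csv(as.data.frame(psa_res$draws), f_psa, row.names = FALSE)
    files <- c(files, f_psa)
  }

  f_json <- file.path(out_dir, "model_result.json")
  report <- list(
    deterministic = list(
      cost_LC = det$LC$total_cost, qaly_LC = det$LC$total_qaly,
      cost_CM = det$CM$total_cost, qaly_CM = det$CM$total_qaly,
      delta_cost = det$delta_cost, delta_qaly = det$delta_qaly,
      icer = det$icer$icer, icer_quadrant = det$icer$quadrant),
    psa = if (!is.null(psa_res)) list(
      n_draws = nrow(psa_res$draws),
      mean_delta_cost = psa_res$mean_delta_cost,
      mean_delta_qaly = psa_res$mean_delta_qaly,
      ceac = psa_res$ceac),
    audit = audit_block(seed, config)
  )
  jsonlite::write_json(report, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  files <- c(files, f_json)
  write_run_log(out_dir, "model", seed, config, files)
  invisible(list(deterministic = det, psa = psa_res))
}

#' @noRd
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = as.integer(rownames(trace$occupancy)),
                   trace$occupancy,
                   disc_cost = c(NA, trace$cost),
                   disc_qaly = c(NA, trace$qaly))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
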