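#' Configure an end-to-end reference-value run
#'
#' @param input path to a cohort CSV, or `NULL` to simulate from
#'   `sim_config`.
#' @param sim_config a [cohort_config()] used when `input` is `NULL`.
#' @param out_dir output directory for tables and models.
#' @param strata age strata for the descriptive tables
#'   (default [decade_strata()]).
#' @param z_mult standard-normal multiplier for the closed-form upper limit.
#' @param boot_reps bootstrap replicates for median CIs.
#' @param levels centile levels for the centile table.
#' @param edf_mu,edf_sigma,edf_nu smoothness budgets for the BCCG fit.
#' @param by_sex fit sex-stratified centile curves.
#' @param run_gamlss run the BCCG centile stage (disable for a
#'   descriptive + log-linear run only).
#' @param centile_ages age grid for the centile table; defaults to integer
#'   ages spanning the cohort.
#' @param seed master seed for every randomized stage.
#' @param verbose `"quiet"`, `"info"` or `"debug"` logging (to stderr).
#' @return a list of class `run_config`.
#' @export
run_config <- function(input = NULL, sim_config = cohort_config(),
                       out_dir = tempfile("nflref_run_"),
                       strata = decade_strata(), z_mult = 1.96,
                       boot_reps = 2000L,
                       levels = c(0.025, 0.05, 0.10, 0.50, 0.90, 0.95, 0.975),
                       edf_mu = 3L, edf_sigma = 1L, edf_nu = 1L,
                       by_sex = TRUE, run_gamlss = TRUE,
                       centile_ages = NULL, seed = 1L,
                       verbose = c("info", "quiet", "debug")) {
  structure(list(input = input, sim_config = sim_config, out_dir = out_dir,
                 strata = strata, z_mult = z_mult,
                 boot_reps = as.integer(boot_reps), levels = levels,
                 edf_mu = edf_mu, edf_sigma = edf_sigma, edf_nu = edf_nu,
                 by_sex = by_sex, run_gamlss = run_gamlss,
                 centile_ages = centile_ages, seed = as.integer(seed),
                 verbose = match.arg(verbose)),
            class = "run_config")
}

.log <- function(config, level, fmt, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[config$verbose]] >= ranks[[level]])
    message(sprintf("[nflref] %s", sprintf(fmt, ...)))
}

.stage <- function(name, config, expr) {
  .log(config, "info", "stage '%s' ...", name)
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full sNfL reference-value pipeline
#'
#' Executes simulate-or-read, the stratified descriptive tables
#' (medians with bootstrap CIs and CLSI reference intervals), the
#' log10-linear fit with its exponentiated upper-limit formula, the BCCG
#' centile fit, the centile table, and per-subject Z-scores, writing each
#' product into `config$out_dir` with metadata headers (package version,
#' seed, config fingerprint). Any stage failure stops the run with the
#' stage name in the error.
#'
#' @param config a [run_config()].
#' @return a list of class `run_summary`: the cohort, tables, fitted
#'   models, Z-score exceedance summary, and the written file paths.
#' @examples
#' \donttest{
#' cfg <- run_config(sim_config = cohort_config(seed = 7),
#'                   out_dir = tempfile(), verbose = "quiet")
#' res <- run_pipeline(cfg)
#' res$tables$reference_intervals
#' }
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  meta <- list(seed = config$seed,
               config = config_fingerprint(config$sim_config))
  cohort <- .stage("cohort", config, {
    if (is.null(config$input)) {
      simulate_cohort(config$sim_config, seed = config$seed)
    } else {
      read_cohort_csv(config$input)
    }
  })
  .log(config, "info", "cohort: %d subjects", nrow(cohort))

  ri <- .stage("descriptive", config,
    stratified_reference_intervals(cohort, config$strata,
                                   reps = config$boot_reps,
                                   seed = config$seed))
  overall <- .stage("descriptive", config,
    reference_interval(cohort$snfl_pg_ml, "all"))

  loglin <- .stage("loglinear", config, fit_loglinear(cohort))
  upper <- .stage("loglinear", config,
                  exponentiate_upper_limit(loglin, z_mult = config$z_mult))

  tables <- list(reference_intervals = as.data.frame(ri))
  models <- list(loglinear_model = loglin, upper_limit_formula = upper)
  ztab <- NULL
  centiles <- NULL
  bccg <- NULL
  if (isTRUE(config$run_gamlss)) {
    bccg <- .stage("gamlss", config,
      fit_bccg_centiles(cohort, edf_mu = config$edf_mu,
                        edf_sigma = config$edf_sigma,
                        edf_nu = config$edf_nu, by_sex = config$by_sex))
    ages <- config$centile_ages
    if (is.null(ages))
      ages <- seq(ceiling(min(cohort$age_years)),
                  floor(max(cohort$age_years)))
    centiles <- .stage("centiles", config,
      centile_table(bccg, ages, levels = config$levels))
    ztab <- .stage("zscores", config, cohort_zscores(bccg, cohort))
    tables$centile_table <- as.data.frame(centiles)
    tables$zscores <- as.data.frame(ztab)
    models$centile_model <- bccg
  }

  paths <- .stage("write", config, {
    p <- write_outputs(tables, models, config$out_dir, meta)
    if (is.null(config$input))
      p["cohort"] <- write_cohort_csv(cohort,
                                      file.path(config$out_dir, "cohort.csv"),
                                      meta)
    p
  })
  .log(config, "info", "wrote %d file(s) to %s", length(paths), config$out_dir)

  structure(list(cohort = cohort,
                 tables = list(reference_intervals = ri,
                               overall_interval = overall,
                               centile_table = centiles),
                 models = list(loglinear = loglin, upper_limit = upper,
                               bccg = bccg),
                 zscores = ztab,
                 zscore_summary = if (!is.null(ztab)) zscore_summary(ztab),
                 paths = paths),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("nflref pipeline run: %d subjects\n", nrow(x$cohort)))
  print(x$tables$reference_intervals)
  print(x$models$upper_limit)
  if (!is.null(x$zscore_summary)) {
    s <- x$zscore_summary
    cat(sprintf("Z-scores: %d scored; |Z| > %.2f: %d (%.1f%%); Z > %.2f: %d (%.1f%%)\n",
                s$n_scored, s$threshold, s$n_abs_gt, 100 * s$frac_abs_gt,
                s$threshold, s$n_gt, 100 * s$frac_gt))
  }
  cat(sprintf("outputs: %s\n", paste(basename(x$paths), collapse = ", ")))
  invisible(x)
}
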