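#' @export
print.bccg_centile_fit <- function(x, ...) {
  cat("Age-normative BCCG (LMS) centile model\n")
  cat(sprintf("  strata: %s; age domain %.1f-%.1f years\n",
              paste(names(x$strata), collapse = ", "),
              x$age_domain[1L], x$age_domain[2L]))
  for (s in names(x$strata)) {
    f <- x$strata[[s]]
    cat(sprintf(
      "  [%s] n = %d, logLik = %.2f, %d cycle(s), edf(mu,sigma,nu) = %d/%d/%d%s\n",
      s, f$n, f$loglik, f$iterations,
      f$edf["mu"], f$edf["sigma"], f$edf["nu"],
      if (f$converged) "" else "  ** NOT CONVERGED **"))
  }
  invisible(x)
}

#' @export
summary.bccg_centile_fit <- function(object, ages = NULL, ...) {
  print(object)
  if (is.null(ages))
    ages <- pretty(object$age_domain, n = 5)
  ages <- ages[ages >= object$age_domain[1L] & ages <= object$age_domain[2L]]
  cat("\nFitted parameters along age:\n")
  for (s in names(object$strata)) {
    sex <- if (object$by_sex) s else "M"
    pars <- bccg_params(object, ages, sex)
    cat(sprintf("  [%s]\n", s))
    print(data.frame(age = ages,
                     mu = round(pars$mu, 3),
                     sigma = round(pars$sigma, 4),
                     nu = round(pars$nu, 4)), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.bccg_centile_fit <- function(object, ...) {
  lapply(object$strata, function(f)
    list(mu = f$coef_mu, sigma = f$coef_sigma, nu = f$coef_nu))
}

#' @export
logLik.bccg_centile_fit <- function(object, ...) {
  ll <- sum(vapply(object$strata, function(f) f$loglik, numeric(1L)))
  df <- sum(vapply(object$strata, function(f) sum(f$edf), numeric(1L)))
  structure(ll, df = df, nobs = nrow(object$data), class = "logLik")
}

#' Predict centiles from a fitted BCCG model
#'
#' @param object a `bccg_centile_fit`.
#' @param age age(s) in years.
#' @param sex `"M"`/`"F"` (recycled).
#' @param p percentile level(s) in (0, 1); recycled against `age` when both
#'   have length > 1, otherwise the grid is the natural elementwise
#'   recycling of equal-length vectors.
#' @param allow_extrapolation permit ages outside the fitted domain.
#' @param ... unused.
#' @return predicted sNfL concentration(s) in pg/ml.
#' @export
predict.bccg_centile_fit <- function(object, age, sex, p = 0.975,
                                     allow_extrapolation = FALSE, ...) {
  pars <- bccg_params(object, age, sex, allow_extrapolation)
  qbccg(p, pars$mu, pars$sigma, pars$nu)
}

#' @export
fitted.bccg_centile_fit <- function(object, ...) {
  bccg_params(object, object$data$age_years, object$data$sex)$mu
}

#' @export
residuals.bccg_centile_fit <- function(object, ...) {
  pars <- bccg_params(object, object$data$age_years, object$data$sex)
  zbccg(object$data$snfl_pg_ml, pars$mu, pars$sigma, pars$nu)
}

#' @export
simulate.bccg_centile_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pars <- bccg_params(object, object$data$age_years, object$data$sex)
  out <- as.data.frame(replicate(nsim,
    rbccg(nrow(pars), pars$mu, pars$sigma, pars$nu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.bccg_centile_fit <- function(x, levels = c(0.025, 0.5, 0.975),
                                  n_grid = 101L, ...) {
  ages <- seq(x$age_domain[1L], x$age_domain[2L], length.out = n_grid)
  dat <- x$data
  op <- graphics::par(mfrow = c(1, length(x$strata)))
  on.exit(graphics::par(op))
  for (s in names(x$strata)) {
    sex <- if (x$by_sex) s else "M"
    sub <- if (x$by_sex) dat[dat$sex == s, ] else dat
    graphics::plot(sub$age_years, sub$snfl_pg_ml,
                   xlab = "age (years)", ylab = "sNfL (pg/ml)",
                   main = sprintf("BCCG centiles [%s]", s),
                   pch = 16, col = "grey50", ...)
    for (p in levels)
      graphics::lines(ages, predict(x, ages, sex, p = p), lwd = 2)
  }
  invisible(x)
}

#' Centile table over an age grid
#'
#' Evaluates [qbccg()] at the model's age/sex-specific parameters over a
#' grid, the tabular counterpart of the centile chart. The default levels
#' cover the 2.5th through 97.5th percentiles used in normative reference
#' databases. Rows are ordered by (sex, age, level); for a fixed age and sex
#' the predictions are strictly increasing in the level.
#'
#' @param model a `bccg_centile_fit`.
#' @param ages ages in years (must lie within the fitted age domain unless
#'   `allow_extrapolation`).
#' @param levels percentile levels in (0, 1).
#' @param sexes which sexes to tabulate (defaults to the fitted strata, or
#'   both sexes for a pooled fit).
#' @param allow_extrapolation permit ages outside the fitted domain.
#' @return a `data.frame` of class `centile_table` with columns `sex`,
#'   `age_years`, `percentile` (probability), `snfl_pg_ml`.
#' @export
centile_table <- function(model, ages,
                          levels = c(0.025, 0.05, 0.10, 0.50,
                                     0.90, 0.95, 0.975),
                          sexes = NULL, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "bccg_centile_fit"))
  if (is.null(sexes)) sexes <- if (model$by_sex) names(model$strata) else c("M", "F")
  levels <- sort(levels)
  grid <- expand.grid(percentile = levels, age_years = sort(ages),
                      sex = sexes, stringsAsFactors = FALSE)
  grid$snfl_pg_ml <- predict(model, grid$age_years, grid$sex,
                             p = grid$percentile,
                             allow_extrapolation = allow_extrapolation)
  out <- grid[, c("sex", "age_years", "percentile", "snfl_pg_ml")]
  rownames(out) <- NULL
  class(out) <- c("centile_table", "data.frame")
  out
}

#' Z-scores of a cohort under a fitted centile model
#'
#' Computes each subject's standard-normal deviate under the fitted
#' age/sex-specific BCCG distribution, with the implied percentile
#' \eqn{\Phi(z)}, plus an exceedance summary: the count and fraction with
#' `|Z| > threshold` and with `Z > threshold` (default 1.96, the outer 5%
#' and upper 2.5% respectively). Subjects whose age falls outside the
#' fitted age domain are flagged (`in_domain = FALSE`), excluded from the
#' summary, and reported in the summary's `n_excluded`.
#'
#' @param model a converged `bccg_centile_fit`.
#' @param cohort an `nfl_cohort` data frame.
#' @param threshold Z threshold for the exceedance summary.
#' @return a `data.frame` of class `zscore_table` (`subject_id`,
#'   `age_years`, `sex`, `snfl_pg_ml`, `z`, `percentile`, `in_domain`) with
#'   a `summary` attribute; see [zscore_summary()].
#' @export
cohort_zscores <- function(model, cohort, threshold = 1.96) {
  stopifnot(inherits(model, "bccg_centile_fit"), is.data.frame(cohort))
  sex <- .normalize_sex(cohort$sex)
  eps <- 1e-8 * max(1, abs(model$age_domain))
  in_domain <- cohort$age_years >= model$age_domain[1L] - eps &
    cohort$age_years <= model$age_domain[2L] + eps
  z <- rep(NA_real_, nrow(cohort))
  if (any(in_domain)) {
    pars <- bccg_params(model, cohort$age_years[in_domain], sex[in_domain])
    z[in_domain] <- zbccg(cohort$snfl_pg_ml[in_domain],
                          pars$mu, pars$sigma, pars$nu)
  }
  out <- data.frame(subject_id = cohort$subject_id,
                    age_years = cohort$age_years, sex = sex,
                    snfl_pg_ml = cohort$snfl_pg_ml,
                    z = z, percentile = stats::pnorm(z),
                    in_domain = in_domain, stringsAsFactors = FALSE)
  zs <- z[in_domain]
  attr(out, "summary") <- list(
    n_scored = length(zs),
    n_excluded = sum(!in_domain),
    threshold = threshold,
    n_abs_gt = sum(abs(zs) > threshold),
    frac_abs_gt = mean(abs(zs) > threshold),
    n_gt = sum(zs > threshold),
    frac_gt = mean(zs > threshold))
  class(out) <- c("zscore_table", "data.frame")
  out
}

#' Exceedance summary of a Z-score table
#'
#' @param ztab result of [cohort_zscores()].
#' @return the summary list: `n_scored`, `n_excluded`, `threshold`,
#'   `n_abs_gt`, `frac_abs_gt`, `n_gt`, `frac_gt`.
#' @export
zscore_summary <- function(ztab) {
  stopifnot(inherits(ztab, "zscore_table"))
  attr(ztab, "summary")
}

#' @export
print.zscore_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Z-scores for %d subject(s)", s$n_scored))
  if (s$n_excluded > 0)
    cat(sprintf(" (%d outside the fitted age domain, excluded)", s$n_excluded))
  cat(sprintf("\n  |Z| > %.2f: %d (%.1f%%);  Z > %.2f: %d (%.1f%%)\n",
              s$threshold, s$n_abs_gt, 100 * s$frac_abs_gt,
              s$threshold, s$n_gt, 100 * s$frac_gt))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 6))
  invisible(x)
}
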