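#' CLSI nonparametric percentile
#'
#' Rank-interpolated order statistic at rank \eqn{r = p(n+1)}, the
#' nonparametric convention of CLSI EP28 for reference-interval bounds.
#' Fractional ranks interpolate linearly between adjacent order statistics;
#' ranks outside `[1, n]` clamp to the extreme order statistics.
#'
#' @param values numeric vector of observations (pg/ml), non-empty.
#' @param p probabilities in (0, 1); may be a vector.
#' @return percentile estimate(s), same length as `p`.
#' @examples
#' clsi_percentile(1:40, 0.025)  # rank 1.025 -> 1.025
#' @export
clsi_percentile <- function(values, p) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be non-empty and finite", call. = FALSE)
  if (any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  s <- sort(values)
  n <- length(s)
  r <- pmin(pmax(p * (n + 1), 1), n)
  lo <- floor(r)
  hi <- ceiling(r)
  s[lo] + (r - lo) * (s[hi] - s[lo])
}

#' Nonparametric reference interval
#'
#' The central range between the 2.5th and 97.5th CLSI percentiles — the
#' interval encompassing 95% of the values of a healthy reference
#' population. Strata smaller than the CLSI minimum of 120 subjects are
#' computed anyway and flagged via `meets_clsi_min_n`.
#'
#' @param values sNfL observations (pg/ml), non-empty.
#' @param stratum_label label for the stratum the values come from.
#' @param lower_p,upper_p percentile bounds (defaults 0.025 and 0.975).
#' @return an object of class `reference_interval`: a list with
#'   `stratum_label`, `n`, `lower`, `upper`, `lower_p`, `upper_p`,
#'   `meets_clsi_min_n`.
#' @export
reference_interval <- function(values, stratum_label = "all",
                               lower_p = 0.025, upper_p = 0.975) {
  b <- clsi_percentile(values, c(lower_p, upper_p))
  structure(list(stratum_label = stratum_label, n = length(values),
                 lower = b[1L], upper = b[2L],
                 lower_p = lower_p, upper_p = upper_p,
                 meets_clsi_min_n = length(values) >= 120L),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("Reference interval [%s]: %.2f-%.2f pg/ml (p%.3g-p%.3g, n = %d%s)\n",
              x$stratum_label, x$lower, x$upper,
              100 * x$lower_p, 100 * x$upper_p, x$n,
              if (x$meets_clsi_min_n) "" else "; below CLSI minimum of 120"))
  invisible(x)
}

#' Default 10-year age strata
#'
#' Decade bins 20-29 ... 60-69, each `[age_low, age_high)`.
#' @return a `data.frame` with columns `label`, `age_low`, `age_high`.
#' @export
decade_strata <- function() {
  lows <- seq(20, 60, by = 10)
  data.frame(label = sprintf("%d-%d", lows, lows + 9),
             age_low = lows, age_high = lows + 10,
             stringsAsFactors = FALSE)
}

#' Percentile-bootstrap confidence interval for the median
#'
#' Resamples the raw values with replacement and takes the percentile
#' interval of the bootstrap medians. Deterministic for a fixed seed.
#'
#' @param values numeric observations, non-empty.
#' @param level confidence level (default 0.95).
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return an object of class `median_summary`: `median`, `ci_low`,
#'   `ci_high`, `level`, `n`, `bootstrap_reps`, `seed`.
#' @export
bootstrap_median_ci <- function(values, level = 0.95, reps = 2000L, seed = 1L) {
  if (length(values) == 0L)
    stop("'values' must be non-empty", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(values)
  boot <- vapply(seq_len(reps),
                 function(i) stats::median(values[sample.int(n, n, replace = TRUE)]),
                 numeric(1L))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(median = stats::median(values),
                 ci_low = ci[1L], ci_high = ci[2L],
                 level = level, n = n,
                 bootstrap_reps = as.integer(reps), seed = as.integer(seed)),
            class = "median_summary")
}

#' @export
print.median_summary <- function(x, ...) {
  cat(sprintf("Median %.2f pg/ml (%.0f%% bootstrap CI %.2f-%.2f, n = %d, %d reps)\n",
              x$median, 100 * x$level, x$ci_low, x$ci_high, x$n, x$bootstrap_reps))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of two groups. Uses
#' the exact null distribution when both groups are tie-free and the smaller
#' has at most 8 observations (enumeration is cheap there), and the
#' tie-corrected normal approximation with continuity correction otherwise.
#' The reported `U` counts pairs where `x` exceeds `y` (ties count 1/2), so
#' `U + U' = n_x * n_y`.
#'
#' @param x,y numeric samples, both non-empty.
#' @param method `"auto"` (default switch rule), `"exact"`, or `"normal"`.
#' @return a list of class `mw_test`: `U`, `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (method == "auto")
    method <- if (!ties && min(length(x), length(y)) <= 8L) "exact" else "normal"
  if (method == "exact") {
    if (ties)
      stop("exact method requires tie-free samples", call. = FALSE)
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    used <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    used <- "normal_approx"
  }
  structure(list(U = U, p_two_sided = p, method = used,
                 n_x = length(x), n_y = length(y)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_x, x$n_y, x$p_two_sided, x$method))
  invisible(x)
}

#' Stratified reference intervals and medians
#'
#' Applies [reference_interval()] and [bootstrap_median_ci()] within each age
#' stratum of a cohort. Strata must be non-overlapping `[age_low, age_high)`
#' bins; empty strata are omitted with a warning, and subjects falling
#' outside every stratum are counted in the `n_outside` attribute rather
#' than silently dropped.
#'
#' @param cohort an `nfl_cohort` data frame (see [simulate_cohort()],
#'   [read_cohort_csv()]).
#' @param strata a data frame with columns `label`, `age_low`, `age_high`
#'   (default [decade_strata()]).
#' @param level confidence level for the median CIs.
#' @param reps bootstrap replicates per stratum.
#' @param seed integer seed for the bootstrap.
#' @param lower_p,upper_p reference-interval percentile bounds.
#' @return a `data.frame` of class `ri_table` with one row per non-empty
#'   stratum: `label`, `n`, `median`, `ci_low`, `ci_high`, `lower`, `upper`,
#'   `clsi_ok`; attribute `n_outside` counts subjects in no stratum.
#' @export
stratified_reference_intervals <- function(cohort, strata = decade_strata(),
                                           level = 0.95, reps = 2000L,
                                           seed = 1L,
                                           lower_p = 0.025, upper_p = 0.975) {
  stopifnot(is.data.frame(cohort), is.data.frame(strata))
  if (any(strata$age_low >= strata$age_high))
    stop("each stratum needs age_low < age_high", call. = FALSE)
  o <- order(strata$age_low)
  s <- strata[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s$age_high[-nrow(s)] > s$age_low[-1L]))
    stop("strata overlap", call. = FALSE)
  in_any <- rep(FALSE, nrow(cohort))
  rows <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    idx <- cohort$age_years >= st$age_low & cohort$age_years < st$age_high
    in_any <- in_any | idx
    v <- cohort$snfl_pg_ml[idx]
    if (length(v) == 0L) {
      warning(sprintf("stratum '%s' is empty; omitted", st$label), call. = FALSE)
      next
    }
    ri <- reference_interval(v, st$label, lower_p, upper_p)
    ms <- bootstrap_median_ci(v, level = level, reps = reps, seed = seed + i)
    rows[[i]] <- data.frame(label = st$label, n = ri$n,
                            median = ms$median, ci_low = ms$ci_low,
                            ci_high = ms$ci_high,
                            lower = ri$lower, upper = ri$upper,
                            clsi_ok = ri$meets_clsi_min_n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "n_outside") <- sum(!in_any)
  class(out) <- c("ri_table", "data.frame")
  out
}

#' @export
print.ri_table <- function(x, digits = 3, ...) {
  cat("Stratified sNfL medians and reference intervals (pg/ml)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  n_out <- attr(x, "n_outside")
  if (!is.null(n_out) && n_out > 0)
    cat(sprintf("(%d subject(s) outside all strata)\n", n_out))
  invisible(x)
}
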