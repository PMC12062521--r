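#' Control settings for the BCCG centile fit
#'
#' @param tol relative change in the log-likelihood below which the outer
#'   cycle stops.
#' @param max_cycles maximum outer cycles over the (mu, sigma, nu) blocks.
#' @param inner_maxit iteration cap for each inner block update.
#' @return a list of control settings.
#' @export
bccg_control <- function(tol = 1e-6, max_cycles = 200L, inner_maxit = 100L) {
  list(tol = tol, max_cycles = as.integer(max_cycles),
       inner_maxit = as.integer(inner_maxit))
}

# --- age-smoother bookkeeping -------------------------------------------
# edf counts the total columns of the design: 1 = constant, 2 = linear
# (standardized age), k >= 3 = intercept + natural cubic spline with k - 1
# basis functions (quantile-placed interior knots).

.smooth_spec <- function(age, edf) {
  edf <- as.integer(edf)
  if (edf < 1L) stop("edf must be >= 1", call. = FALSE)
  if (edf == 1L) return(list(type = "const", edf = 1L))
  center <- mean(age); scale <- stats::sd(age)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  if (edf == 2L)
    return(list(type = "linear", edf = 2L, center = center, scale = scale))
  B <- splines::ns(age, df = edf - 1L)
  list(type = "ns", edf = edf,
       knots = as.numeric(attr(B, "knots")),
       boundary = as.numeric(attr(B, "Boundary.knots")),
       center = center, scale = scale)
}

.smooth_design <- function(spec, age) {
  switch(spec$type,
         const = matrix(1, length(age), 1L),
         linear = cbind(1, (age - spec$center) / spec$scale),
         ns = cbind(1, splines::ns(age, knots = spec$knots,
                                   Boundary.knots = spec$boundary)))
}

# linear predictor -> parameter (mu, sigma: log link; nu: identity)
.param_eval <- function(spec, coef, age, link) {
  eta <- drop(.smooth_design(spec, age) %*% coef)
  if (link == "log") exp(eta) else eta
}

# --- single-stratum fit --------------------------------------------------

.fit_bccg_stratum <- function(age, y, edf_mu, edf_sigma, edf_nu, control) {
  n <- length(y)
  if (n < 30L)
    stop(sprintf("degenerate stratum: %d subjects (need >= 30)", n),
         call. = FALSE)
  if (any(y <= 0))
    stop("sNfL concentrations must be strictly positive", call. = FALSE)
  spec_mu <- .smooth_spec(age, edf_mu)
  spec_sigma <- .smooth_spec(age, edf_sigma)
  spec_nu <- .smooth_spec(age, edf_nu)
  Xm <- .smooth_design(spec_mu, age)
  Xs <- .smooth_design(spec_sigma, age)
  Xn <- .smooth_design(spec_nu, age)

  # initialize: log-median from an OLS fit of log(y), sigma from its
  # residual spread, nu at 1 (the LMS convention's starting shape)
  ly <- log(y)
  bm <- qr.coef(qr(Xm), ly)
  bs <- c(log(stats::sd(ly - drop(Xm %*% bm))), rep(0, ncol(Xs) - 1L))
  bn <- c(1, rep(0, ncol(Xn) - 1L))

  loglik <- function(bm, bs, bn) {
    mu <- exp(drop(Xm %*% bm))
    sigma <- exp(drop(Xs %*% bs))
    nu <- drop(Xn %*% bn)
    # exp() under/overflow during a line-search overshoot: reject the step
    if (any(!is.finite(mu)) || any(mu <= 0) ||
        any(!is.finite(sigma)) || any(sigma <= 0) || any(!is.finite(nu)))
      return(-Inf)
    ll <- sum(dbccg(y, mu, sigma, nu, log = TRUE))
    if (!is.finite(ll)) -Inf else ll
  }
  negll_cap <- function(ll) if (is.finite(ll)) -ll else 1e10
  # analytic score of the mu block on the eta = log(mu) scale:
  # d logf / d eta = z * (y/mu)^nu / sigma - nu   (-> z/sigma as nu -> 0)
  grad_mu <- function(bm, bs, bn) {
    mu <- exp(drop(Xm %*% bm))
    sigma <- exp(drop(Xs %*% bs))
    nu <- drop(Xn %*% bn)
    if (any(!is.finite(mu)) || any(mu <= 0))
      return(rep(0, length(bm)))
    z <- zbccg(y, mu, sigma, nu)
    t_ <- ifelse(abs(nu) <= .bccg_eps, 1, (y / mu)^nu)
    g <- drop(crossprod(Xm, z * t_ / sigma - nu))
    if (any(!is.finite(g))) rep(0, length(bm)) else g
  }

  ll <- loglik(bm, bs, bn)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  opt_ctl <- list(maxit = control$inner_maxit, reltol = 1e-12)
  for (iter in seq_len(control$max_cycles)) {
    bm <- stats::optim(bm, fn = function(b) negll_cap(loglik(b, bs, bn)),
                       gr = function(b) -grad_mu(b, bs, bn),
                       method = "BFGS", control = opt_ctl)$par
    bs <- stats::optim(bs, fn = function(b) negll_cap(loglik(bm, b, bn)),
                       method = "BFGS", control = opt_ctl)$par
    bn <- stats::optim(bn, fn = function(b) negll_cap(loglik(bm, bs, b)),
                       method = "BFGS", control = opt_ctl)$par
    ll_new <- loglik(bm, bs, bn)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < control$tol * (abs(ll_new) + 0.1)) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  if (!converged)
    stop(sprintf(
      "BCCG fit did not converge in %d cycles; last log-likelihoods: %s",
      control$max_cycles,
      paste(sprintf("%.6f", utils::tail(trace, 5L)), collapse = ", ")),
      call. = FALSE)
  list(spec_mu = spec_mu, spec_sigma = spec_sigma, spec_nu = spec_nu,
       coef_mu = unname(bm), coef_sigma = unname(bs), coef_nu = unname(bn),
       loglik = ll, iterations = iter, converged = converged,
       edf = c(mu = spec_mu$edf, sigma = spec_sigma$edf, nu = spec_nu$edf),
       n = n, age_range = range(age))
}

#' Fit age-normative BCCG (LMS) centile curves
#'
#' GAMLSS-type fit of the Box-Cox Cole-Green distribution with age-varying
#' parameters: the median \eqn{\mu} gets a log link with a natural cubic
#' regression spline in age (default 3 degrees of freedom), while
#' \eqn{\sigma} (log link) and \eqn{\nu} (identity link) are constant by
#' default. The likelihood is maximized by cycling Newton-type (BFGS) block
#' updates over the three parameter vectors until the log-likelihood changes
#' by less than `tol` relative, in the style of the Rigby-Stasinopoulos
#' algorithm; the fit is deterministic given data and settings. With
#' `by_sex = TRUE` (the default, matching sex-stratified centile charts)
#' each sex is fitted separately; `by_sex = FALSE` fits a single pooled
#' curve set.
#'
#' @param cohort an `nfl_cohort` data frame (`age_years`, `sex`,
#'   `snfl_pg_ml > 0`), at least 30 subjects per fitted stratum.
#' @param edf_mu,edf_sigma,edf_nu smoothness budget per distribution
#'   parameter: 1 = constant, 2 = linear in age, k >= 3 = natural cubic
#'   spline with k total coefficients.
#' @param by_sex fit each sex separately (`TRUE`) or pooled (`FALSE`).
#' @param control see [bccg_control()].
#' @return an object of class `bccg_centile_fit` with per-stratum smooth
#'   parameter functions, fit metadata (log-likelihood, cycles, convergence
#'   flag, effective degrees of freedom) and the training data. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `residuals` (Z-scores),
#'   `fitted`, `simulate`, `logLik`.
#' @seealso [centile_table()], [cohort_zscores()], [bccg]
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_total = 400, seed = 2))
#' fit <- fit_bccg_centiles(cohort)
#' predict(fit, age = 40, sex = "F", p = 0.975)
#' @export
fit_bccg_centiles <- function(cohort, edf_mu = 3L, edf_sigma = 1L,
                              edf_nu = 1L, by_sex = TRUE,
                              control = bccg_control()) {
  stopifnot(is.data.frame(cohort))
  sex <- .normalize_sex(cohort$sex)
  groups <- if (by_sex) split(seq_len(nrow(cohort)), sex)
            else list(all = seq_len(nrow(cohort)))
  strata <- lapply(groups, function(idx) {
    .fit_bccg_stratum(cohort$age_years[idx], cohort$snfl_pg_ml[idx],
                      edf_mu, edf_sigma, edf_nu, control)
  })
  structure(list(strata = strata, by_sex = by_sex,
                 age_domain = range(cohort$age_years),
                 edf = c(mu = as.integer(edf_mu),
                         sigma = as.integer(edf_sigma),
                         nu = as.integer(edf_nu)),
                 data = data.frame(subject_id = cohort$subject_id,
                                   age_years = cohort$age_years,
                                   sex = sex,
                                   snfl_pg_ml = cohort$snfl_pg_ml,
                                   stringsAsFactors = FALSE),
                 call = match.call()),
            class = "bccg_centile_fit")
}

# map subjects to their stratum fit; returns character vector of names
.stratum_of <- function(model, sex) {
  if (model$by_sex) .normalize_sex(sex) else rep("all", length(sex))
}

#' Age/sex-specific BCCG parameters from a fitted centile model
#'
#' @param model a `bccg_centile_fit`.
#' @param age age(s) in years.
#' @param sex `"M"`/`"F"` (recycled; ignored by pooled fits).
#' @param allow_extrapolation evaluate outside the fitted age domain? The
#'   default refuses, since centile estimates outside the observed ages are
#'   unreliable.
#' @return a `data.frame` with columns `age_years`, `sex`, `mu`, `sigma`,
#'   `nu`.
#' @export
bccg_params <- function(model, age, sex, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "bccg_centile_fit"))
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(.normalize_sex(sex), n)
  # tolerate floating-point jitter at the domain edges (serialization keeps
  # ~15 significant digits)
  eps <- 1e-8 * max(1, abs(model$age_domain))
  if (!allow_extrapolation &&
      (any(age < model$age_domain[1L] - eps) ||
       any(age > model$age_domain[2L] + eps)))
    stop(sprintf(
      "age outside the fitted domain [%.1f, %.1f]; set allow_extrapolation = TRUE to override",
      model$age_domain[1L], model$age_domain[2L]), call. = FALSE)
  strat <- .stratum_of(model, sex)
  mu <- sigma <- nu <- numeric(n)
  for (s in unique(strat)) {
    f <- model$strata[[s]]
    if (is.null(f)) stop(sprintf("no fitted stratum '%s'", s), call. = FALSE)
    idx <- strat == s
    mu[idx] <- .param_eval(f$spec_mu, f$coef_mu, age[idx], "log")
    sigma[idx] <- .param_eval(f$spec_sigma, f$coef_sigma, age[idx], "log")
    nu[idx] <- .param_eval(f$spec_nu, f$coef_nu, age[idx], "identity")
  }
  data.frame(age_years = age, sex = sex, mu = mu, sigma = sigma, nu = nu,
             stringsAsFactors = FALSE)
}
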