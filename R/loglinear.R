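#' Log10-linear regression of sNfL on age and sex
#'
#' Fits ordinary least squares of `log10(snfl_pg_ml)` on age (years) and a
#' female indicator (female = 1, male = 0):
#' \deqn{\log_{10} \mathrm{sNfL} = \beta_0 + \beta_{\mathrm{age}}
#'   \cdot \mathrm{age} + \beta_{\mathrm{female}} \cdot [\mathrm{female}]}
#' The residual standard deviation (divisor \eqn{n - 3}) is the "standard
#' error of the model" used by [exponentiate_upper_limit()] to build the
#' closed-form 97.5th-percentile cut-off. Coefficient p-values come from the
#' t distribution.
#'
#' @param cohort an `nfl_cohort` data frame with columns `age_years`, `sex`
#'   and strictly positive `snfl_pg_ml`; both sexes and at least two
#'   distinct ages must be present.
#' @return an object of class `nfl_loglin`: `intercept`, `beta_age`,
#'   `beta_female` (all on the log10 scale), `residual_se`, `n`, `p_age`,
#'   `p_female`, and the underlying `lm` fit.
#' @seealso [exponentiate_upper_limit()], [predict.nfl_loglin()]
#' @export
fit_loglinear <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  y <- cohort$snfl_pg_ml
  if (any(y <= 0))
    stop("sNfL concentrations must be strictly positive for the log10 transform",
         call. = FALSE)
  sex <- .normalize_sex(cohort$sex)
  if (length(unique(sex)) < 2L)
    stop("rank-deficient design: the female indicator needs both sexes present",
         call. = FALSE)
  if (length(unique(cohort$age_years)) < 2L)
    stop("rank-deficient design: at least two distinct ages required",
         call. = FALSE)
  dat <- data.frame(log10_snfl = log10(y),
                    age = cohort$age_years,
                    female = as.numeric(sex == "F"))
  fit <- stats::lm(log10_snfl ~ age + female, data = dat)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(intercept = unname(co["(Intercept)", 1L]),
                 beta_age = unname(co["age", 1L]),
                 beta_female = unname(co["female", 1L]),
                 residual_se = sm$sigma,
                 n = nrow(dat),
                 p_age = unname(co["age", 4L]),
                 p_female = unname(co["female", 4L]),
                 lm = fit),
            class = "nfl_loglin")
}

#' Published log10-linear fit for healthy Thai adults
#'
#' The reported coefficients of the log10-linear sNfL model in a reference
#' cohort of 223 healthy Thai adults:
#' log10 sNfL = 0.012*age - 0.059*female + 0.326, model standard error
#' 0.166, sex-effect p = 0.008, age p < 0.001. Shipped as a frozen fixture
#' so the closed-form upper-limit operations are usable without the raw
#' cohort (which is not publicly deposited). Note the printed coefficients
#' are rounded: reconstructing the multiplicative intercept from them gives
#' about 4.48 rather than the published 4.470 (a ~0.25% discrepancy).
#'
#' @return an `nfl_loglin`-compatible list (no underlying `lm`).
#' @export
published_loglinear_fit <- function() {
  structure(list(intercept = 0.326, beta_age = 0.012, beta_female = -0.059,
                 residual_se = 0.166, n = 223L,
                 p_age = NA_real_,   # reported only as < 0.001
                 p_female = 0.008,
                 lm = NULL),
            class = "nfl_loglin")
}

#' @export
print.nfl_loglin <- function(x, ...) {
  cat("Log10-linear sNfL model (female = 1, male = 0)\n")
  cat(sprintf("  log10(sNfL) = %.4g + %.4g * age %s %.4g * female\n",
              x$intercept, x$beta_age,
              if (x$beta_female < 0) "-" else "+", abs(x$beta_female)))
  cat(sprintf("  residual SE = %.4g (log10 units), n = %d\n",
              x$residual_se, x$n))
  invisible(x)
}

#' @export
summary.nfl_loglin <- function(object, ...) {
  print(object)
  cat(sprintf("  p(age) = %s, p(female) = %s\n",
              stats::format.pval(object$p_age),
              stats::format.pval(object$p_female)))
  if (!is.null(object$lm)) {
    cat("\nUnderlying lm fit:\n")
    print(summary(object$lm))
  }
  invisible(object)
}

#' @export
coef.nfl_loglin <- function(object, ...) {
  c(intercept = object$intercept, beta_age = object$beta_age,
    beta_female = object$beta_female)
}

#' Predict from the log10-linear model
#'
#' @param object an `nfl_loglin` fit.
#' @param age age(s) in years.
#' @param sex `"M"`/`"F"` (recycled).
#' @param type `"median"` for the back-transformed regression line,
#'   `"upper"` for the predicted 97.5th percentile (adds
#'   `z_mult * residual_se` on the log10 scale before exponentiating).
#' @param z_mult standard-normal multiplier for `type = "upper"`.
#' @param ... unused.
#' @return predicted sNfL in pg/ml.
#' @export
predict.nfl_loglin <- function(object, age, sex, type = c("median", "upper"),
                               z_mult = 1.96, ...) {
  type <- match.arg(type)
  sex <- .normalize_sex(sex)
  lin <- object$intercept + object$beta_age * age +
    object$beta_female * (sex == "F")
  if (type == "upper") lin <- lin + z_mult * object$residual_se
  10^lin
}

#' Closed-form exponentiated upper-limit formula
#'
#' Turns a log10-linear fit into the multiplicative cut-off formula
#' \deqn{\mathrm{sNfL}_{97.5} = \mathrm{scale} \cdot
#'   \mathrm{age\_factor}^{\mathrm{age}} \cdot
#'   \mathrm{female\_factor}^{[\mathrm{female}]}}
#' with `scale = 10^(intercept + z_mult * residual_se)`,
#' `age_factor = 10^beta_age` and `female_factor = 10^beta_female`. With the
#' published coefficients this is the familiar
#' 4.47 x 1.028^age x 0.873^female pg/ml rule.
#'
#' @param fit an `nfl_loglin` object (fitted or [published_loglinear_fit()]).
#' @param z_mult standard-normal quantile; 1.96 gives the 97.5th percentile
#'   under the log-normal residual assumption, 0 the median line.
#' @return an object of class `upper_limit_formula`: `scale`, `age_factor`,
#'   `female_factor`, `z_mult`, plus the source log10 coefficients.
#' @export
exponentiate_upper_limit <- function(fit, z_mult = 1.96) {
  stopifnot(inherits(fit, "nfl_loglin") ||
              all(c("intercept", "beta_age", "beta_female", "residual_se")
                  %in% names(fit)))
  structure(list(scale = 10^(fit$intercept + z_mult * fit$residual_se),
                 age_factor = 10^fit$beta_age,
                 female_factor = 10^fit$beta_female,
                 z_mult = z_mult,
                 intercept = fit$intercept,
                 beta_age = fit$beta_age,
                 beta_female = fit$beta_female,
                 residual_se = fit$residual_se),
            class = "upper_limit_formula")
}

#' @export
print.upper_limit_formula <- function(x, ...) {
  cat(sprintf("sNfL upper limit = %.4g x %.4g^age x %.4g^female pg/ml (z = %g)\n",
              x$scale, x$age_factor, x$female_factor, x$z_mult))
  invisible(x)
}

#' Evaluate the upper-limit formula
#'
#' @param formula an `upper_limit_formula` object.
#' @param age age(s) in years, >= 0.
#' @param sex `"M"`/`"F"` (recycled).
#' @return predicted upper-limit sNfL in pg/ml.
#' @examples
#' f <- exponentiate_upper_limit(published_loglinear_fit())
#' predict_upper_limit(f, age = 40, sex = "F")
#' @export
predict_upper_limit <- function(formula, age, sex) {
  stopifnot(inherits(formula, "upper_limit_formula"))
  if (any(age < 0))
    stop("'age' must be non-negative", call. = FALSE)
  sex <- .normalize_sex(sex)
  formula$scale * formula$age_factor^age *
    formula$female_factor^(sex == "F")
}

#' @export
predict.upper_limit_formula <- function(object, age, sex, ...) {
  predict_upper_limit(object, age, sex)
}
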