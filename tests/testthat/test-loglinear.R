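make_noiseless_cohort <- function() {
  grid <- expand.grid(age = seq(20, 69, by = 0.5), female = c(0, 1))
  data.frame(subject_id = sprintf("N%04d", seq_len(nrow(grid))),
             age_years = grid$age,
             sex = ifelse(grid$female == 1, "F", "M"),
             snfl_pg_ml = 10^(0.326 + 0.012 * grid$age - 0.059 * grid$female),
             stringsAsFactors = FALSE)
}

test_that("exact log10-linear data is recovered to machine precision", {
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_loglinear(make_noiseless_cohort()))
  expect_equal(fit$intercept, 0.326, tolerance = 1e-10)
  expect_equal(fit$beta_age, 0.012, tolerance = 1e-10)
  expect_equal(fit$beta_female, -0.059, tolerance = 1e-10)
  expect_lt(fit$residual_se, 1e-10)
  expect_equal(fit$n, nrow(make_noiseless_cohort()))
})

test_that("the generator slope is recovered within sampling error", {
  cohort <- simulate_cohort(cohort_config(seed = 41))
  fit <- fit_loglinear(cohort)
  se_age <- summary(fit$lm)$coefficients["age", 2]
  expect_lt(abs(fit$beta_age - 0.012), 3 * se_age)
  # residual spread near the generating log10 dispersion sigma/ln(10)
  expect_equal(fit$residual_se, 0.38 / log(10), tolerance = 0.15)
  expect_lt(fit$p_age, 0.001)
})

test_that("degenerate designs and non-positive concentrations are refused", {
  co <- make_noiseless_cohort()
  males <- co[co$sex == "M", ]
  expect_error(fit_loglinear(males), "female indicator")
  one_age <- co[abs(co$age_years - 40) < 1e-9, ]
  expect_error(fit_loglinear(one_age), "distinct ages")
  co$snfl_pg_ml[1] <- 0
  expect_error(fit_loglinear(co), "positive")
})

test_that("shifting all log10 values moves only the intercept", {
  co <- simulate_cohort(cohort_config(seed = 43))
  f1 <- fit_loglinear(co)
  co$snfl_pg_ml <- co$snfl_pg_ml * 10^0.25
  f2 <- fit_loglinear(co)
  expect_equal(f2$intercept - f1$intercept, 0.25, tolerance = 1e-10)
  expect_equal(f2$beta_age, f1$beta_age, tolerance = 1e-12)
  expect_equal(f2$beta_female, f1$beta_female, tolerance = 1e-12)
  expect_equal(f2$residual_se, f1$residual_se, tolerance = 1e-12)
})

test_that("exponentiation reproduces the published cut-off formula", {
  f <- exponentiate_upper_limit(published_loglinear_fit())
  expect_equal(round(f$age_factor, 3), 1.028)
  expect_equal(round(f$female_factor, 3), 0.873)
  # rounded printed inputs reconstruct the printed 4.470 to ~0.3%
  expect_equal(f$scale, 4.470, tolerance = 0.005)
  # z = 0 gives the median line; log10(scale) inverts to the intercept
  f0 <- exponentiate_upper_limit(published_loglinear_fit(), z_mult = 0)
  expect_equal(f0$scale, 10^0.326)
  expect_equal(log10(f$scale) - 1.96 * 0.166, 0.326, tolerance = 1e-12)
})

test_that("the upper-limit formula evaluates and scales as printed", {
  f <- exponentiate_upper_limit(published_loglinear_fit())
  expect_equal(predict_upper_limit(f, 0, "M"), f$scale)
  # plausibility cross-check against the centile-model value 6.9 at age 20
  expect_equal(predict_upper_limit(f, 20, "F"), 6.9, tolerance = 0.02)
  ages <- seq(0, 70, by = 5)
  expect_equal(predict_upper_limit(f, ages, "F") /
                 predict_upper_limit(f, ages, "M"),
               rep(f$female_factor, length(ages)))
  expect_true(all(diff(predict_upper_limit(f, ages, "M")) > 0))
  expect_error(predict_upper_limit(f, -3, "M"), "non-negative")
})

test_that("exponentiated predictions round-trip to the linear predictor", {
  fit <- fit_loglinear(simulate_cohort(cohort_config(seed = 47)))
  f <- exponentiate_upper_limit(fit)
  ages <- c(20, 35.5, 50, 69)
  for (sex in c("M", "F")) {
    lin <- fit$intercept + fit$beta_age * ages +
      fit$beta_female * (sex == "F") + 1.96 * fit$residual_se
    expect_equal(log10(predict_upper_limit(f, ages, sex)), lin,
                 tolerance = 1e-12)
    expect_equal(predict(fit, ages, sex, type = "upper"),
                 predict_upper_limit(f, ages, sex), tolerance = 1e-12)
  }
})

test_that("about 2.5% of a log-normal cohort exceeds its fitted 97.5% line", {
  cfg <- cohort_config(n_total = 20000, nu = 0, seed = 53)
  cohort <- simulate_cohort(cfg)
  f <- exponentiate_upper_limit(fit_loglinear(cohort))
  frac <- mean(cohort$snfl_pg_ml >
                 predict_upper_limit(f, cohort$age_years, cohort$sex))
  expect_lt(abs(frac - 0.025), 0.01)
})
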