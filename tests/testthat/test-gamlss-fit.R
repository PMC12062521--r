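# shared fitted model for this file (n = 2000 per sex, generator defaults)
fit_cache <- local({
  cohort <- simulate_cohort(cohort_config(n_total = 4000, female_fraction = 0.5,
                                          sex_mode = "fixed", seed = 4))
  list(cohort = cohort, fit = fit_bccg_centiles(cohort))
})

test_that("the fitted median curve recovers the generating curve within 5%", {
  cfg <- cohort_config()
  ages <- 20:60
  for (s in c("M", "F")) {
    mu_hat <- bccg_params(fit_cache$fit, ages, s, allow_extrapolation = TRUE)$mu
    mu_true <- true_centile(cfg, ages, s, 0.5)
    expect_lt(max(abs(mu_hat / mu_true - 1)), 0.05)
  }
  # bias at interior ages is small
  mid <- bccg_params(fit_cache$fit, 45, "M")$mu
  expect_lt(abs(mid / true_centile(cfg, 45, "M", 0.5) - 1), 0.05)
})

test_that("scale and shape parameters are recovered across replicate cohorts", {
  sig <- nu <- c()
  for (s in 1:4) {
    co <- simulate_cohort(cohort_config(n_total = 4000, female_fraction = 0.5,
                                        sex_mode = "fixed", seed = 200 + s))
    fit <- fit_bccg_centiles(co)
    for (st in names(fit$strata)) {
      sig <- c(sig, exp(fit$strata[[st]]$coef_sigma[1]))
      nu <- c(nu, fit$strata[[st]]$coef_nu[1])
    }
  }
  expect_lt(abs(mean(sig) / 0.38 - 1), 0.15)
  expect_lt(abs(mean(nu) / 0.3 - 1), 0.15)
})

test_that("in-sample Z-scores are calibrated", {
  z <- residuals(fit_cache$fit)
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
})

test_that("refitting identical inputs reproduces the model exactly", {
  refit <- fit_bccg_centiles(fit_cache$cohort)
  expect_identical(coef(refit), coef(fit_cache$fit))
  expect_equal(logLik(refit), logLik(fit_cache$fit))
  expect_true(all(vapply(refit$strata, function(f) f$converged, logical(1))))
})

test_that("centile tables are monotone with the median equal to mu", {
  tab <- centile_table(fit_cache$fit, ages = c(25, 40, 55))
  expect_equal(sort(unique(tab$percentile)),
               c(0.025, 0.05, 0.10, 0.50, 0.90, 0.95, 0.975))
  for (s in unique(tab$sex)) for (a in unique(tab$age_years)) {
    row <- tab[tab$sex == s & tab$age_years == a, ]
    expect_true(all(diff(row$snfl_pg_ml) > 0))   # non-crossing in p
    expect_equal(row$snfl_pg_ml[row$percentile == 0.5],
                 bccg_params(fit_cache$fit, a, s)$mu, tolerance = 1e-12)
  }
})

test_that("Z-scores vanish on the median curve and summarize exceedance", {
  model <- truth_model(cohort_config())
  cohort <- data.frame(subject_id = c("a", "b"), age_years = c(30, 55),
                       sex = c("M", "F"),
                       snfl_pg_ml = bccg_params(model, c(30, 55),
                                                c("M", "F"))$mu)
  zt <- cohort_zscores(model, cohort)
  expect_equal(zt$z, c(0, 0), tolerance = 1e-12)
  expect_equal(zt$percentile, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("exceedance fractions under the true model match the nominal tails", {
  cfg <- cohort_config(n_total = 50000, seed = 61)
  cohort <- simulate_cohort(cfg)
  zt <- cohort_zscores(truth_model(cfg), cohort)
  s <- zscore_summary(zt)
  expect_lt(abs(s$frac_gt - 0.025), 0.005)
  expect_lt(abs(s$frac_abs_gt - 0.05), 0.008)
  expect_equal(s$n_scored + s$n_excluded, nrow(cohort))
})

test_that("out-of-domain subjects are flagged and excluded from the summary", {
  model <- truth_model(cohort_config(), age_domain = c(20, 70))
  cohort <- data.frame(subject_id = c("in", "out"), age_years = c(40, 80),
                       sex = c("M", "M"), snfl_pg_ml = c(7, 7))
  zt <- cohort_zscores(model, cohort)
  expect_equal(zt$in_domain, c(TRUE, FALSE))
  expect_true(is.na(zt$z[2]))
  expect_equal(zscore_summary(zt)$n_excluded, 1L)
  expect_error(predict(model, 80, "M", p = 0.5), "domain")
})

test_that("with nu = 0 the centile fit agrees with the exponentiated formula", {
  cfg <- cohort_config(n_total = 10000, nu = 0, female_fraction = 0.5,
                       sex_mode = "fixed", seed = 71)
  cohort <- simulate_cohort(cfg)
  gam <- fit_bccg_centiles(cohort)
  form <- exponentiate_upper_limit(fit_loglinear(cohort))
  ages <- 20:60
  for (s in c("M", "F")) {
    q_gam <- predict(gam, ages, s, p = 0.975, allow_extrapolation = TRUE)
    q_lin <- predict_upper_limit(form, ages, s)
    expect_lt(max(abs(q_gam / q_lin - 1)), 0.03)
  }
})

test_that("degenerate strata and invalid inputs are refused", {
  tiny <- simulate_cohort(cohort_config(n_total = 40, seed = 81))
  expect_error(fit_bccg_centiles(tiny), "30")  # < 30 per sex stratum
  co <- fit_cache$cohort
  co$snfl_pg_ml[1] <- -1
  expect_error(fit_bccg_centiles(co), "positive")
})

test_that("pooled and flexible-sigma fits converge too", {
  co <- simulate_cohort(cohort_config(n_total = 1000, seed = 91))
  pooled <- fit_bccg_centiles(co, by_sex = FALSE)
  expect_named(pooled$strata, "all")
  expect_true(pooled$strata$all$converged)
  # pooled fit predicts identically for both sexes
  expect_equal(predict(pooled, 40, "M", p = 0.9),
               predict(pooled, 40, "F", p = 0.9))
  flex <- fit_bccg_centiles(co, edf_sigma = 2L)
  expect_true(all(vapply(flex$strata, function(f) f$converged, logical(1))))
})
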