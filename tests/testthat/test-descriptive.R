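test_that("CLSI percentile matches hand-computed ranks", {
  expect_equal(clsi_percentile(c(1, 2, 3, 4, 5), 0.5), 3)
  # rank r = 0.025 * 41 = 1.025 -> interpolate between 1st and 2nd order stats
  expect_equal(clsi_percentile(1:40, 0.025), 1.025)
  expect_equal(clsi_percentile(1:40, 0.975), 39.975)
  expect_error(clsi_percentile(numeric(0), 0.5), "non-empty")
  expect_error(clsi_percentile(1:5, 0), "inside")
})

test_that("CLSI percentile agrees with independent oracles on random instances", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:60, 1)
    v <- round(rlnorm(n, 1, 0.7), 3)
    p <- runif(1, 0.01, 0.99)
    expect_equal(clsi_percentile(v, p), oracle_percentile(v, p),
                 tolerance = 1e-12)
    expect_equal(clsi_percentile(v, p),
                 unname(quantile(v, p, type = 6)), tolerance = 1e-12)
  }
})

test_that("percentiles are monotone in p and permutation invariant", {
  set.seed(7)
  v <- rlnorm(37, 1.5, 0.4)
  ps <- sort(runif(20, 0.01, 0.99))
  expect_true(all(diff(clsi_percentile(v, ps)) >= 0))
  ri1 <- reference_interval(v)
  ri2 <- reference_interval(sample(v))
  expect_equal(ri1$lower, ri2$lower)
  expect_equal(ri1$upper, ri2$upper)
})

test_that("reference intervals carry the CLSI sample-size flag", {
  ri <- reference_interval(rep(5, 200))
  expect_equal(c(ri$lower, ri$upper), c(5, 5))
  expect_true(ri$meets_clsi_min_n)
  # a 57-subject decade stratum is below the minimum of 120
  expect_false(reference_interval(rlnorm(57))$meets_clsi_min_n)
  expect_true(reference_interval(rlnorm(120))$meets_clsi_min_n)
})

test_that("the pooled interval encompasses about 95% of fresh draws", {
  cfg <- cohort_config(n_total = 10000, seed = 31)
  ref <- simulate_cohort(cfg)
  ri <- reference_interval(ref$snfl_pg_ml)
  fresh <- simulate_cohort(cfg, seed = 32)
  inside <- mean(fresh$snfl_pg_ml >= ri$lower & fresh$snfl_pg_ml <= ri$upper)
  expect_lt(abs(inside - 0.95), 0.01)
})

test_that("stratified tables reproduce the decade and merged-bin counts", {
  cohort <- simulate_cohort(cohort_config(seed = 13))
  tab <- stratified_reference_intervals(cohort, reps = 200, seed = 1)
  expect_equal(tab$n, c(57L, 58L, 59L, 37L, 12L))
  expect_false(any(tab$clsi_ok))
  # rising generating median => nondecreasing stratum medians
  expect_true(all(diff(tab$median) >= 0))
  merged <- data.frame(label = c("20-39", "40-69"),
                       age_low = c(20, 40), age_high = c(40, 70))
  tab2 <- stratified_reference_intervals(cohort, merged, reps = 200, seed = 1)
  expect_equal(tab2$n, c(115L, 108L))
  # even the merged bins sit just below the CLSI minimum of 120
  expect_equal(tab2$clsi_ok, c(FALSE, FALSE))
})

test_that("empty strata are omitted with a warning and outsiders counted", {
  cohort <- simulate_cohort(cohort_config(seed = 13))
  wide <- data.frame(label = c("0-9", "20-69"),
                     age_low = c(0, 20), age_high = c(10, 70))
  expect_warning(tab <- stratified_reference_intervals(cohort, wide,
                                                       reps = 100, seed = 1),
                 "empty")
  expect_equal(tab$label, "20-69")
  narrow <- data.frame(label = "30-39", age_low = 30, age_high = 40)
  tab2 <- stratified_reference_intervals(cohort, narrow, reps = 100, seed = 1)
  expect_equal(attr(tab2, "n_outside"), 223L - 58L)
  bad <- data.frame(label = c("a", "b"), age_low = c(20, 25),
                    age_high = c(30, 35))
  expect_error(stratified_reference_intervals(cohort, bad), "overlap")
})

test_that("bootstrap median CIs are deterministic and degenerate correctly", {
  ms <- bootstrap_median_ci(rep(4.2, 50), seed = 5)
  expect_equal(ms$ci_low, 4.2)
  expect_equal(ms$ci_high, 4.2)
  v <- rlnorm(80, 1.6, 0.4)
  expect_identical(bootstrap_median_ci(v, seed = 9),
                   bootstrap_median_ci(v, seed = 9))
  ms <- bootstrap_median_ci(v, seed = 9)
  expect_lte(ms$ci_low, ms$median)
  expect_gte(ms$ci_high, ms$median)
})

test_that("bootstrap CIs cover the true median at about the nominal rate", {
  cfg <- cohort_config()
  mu_true <- true_centile(cfg, 39, "M", 0.5)
  set.seed(77)
  hits <- vapply(1:200, function(i) {
    y <- rbccg(500, mu_true, cfg$sigma, cfg$nu)
    ms <- bootstrap_median_ci(y, reps = 500, seed = i)
    ms$ci_low <= mu_true && mu_true <= ms$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("Mann-Whitney matches enumeration and obeys the complement identity", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_two_sided, 1 / 3, tolerance = 1e-12)
  # identical multisets (forced normal path by ties): p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "normal_approx")
  expect_equal(same$p_two_sided, 1, tolerance = 0.01)
  set.seed(19)
  for (i in 1:25) {
    x <- sample(1:100, 6); y <- sample(101:200, 7) / 10
    U_x <- mann_whitney_u(x, y)$U
    U_y <- mann_whitney_u(y, x)$U
    expect_equal(U_x + U_y, length(x) * length(y))
  }
})

test_that("normal approximation tracks the exact null for small samples", {
  set.seed(23)
  for (i in 1:20) {
    x <- runif(5); y <- runif(5) + runif(1, -0.5, 0.5)
    p_norm <- mann_whitney_u(x, y, method = "normal")$p_two_sided
    p_enum <- oracle_mw_exact_p(x, y)
    expect_lt(abs(p_norm - p_enum), 0.05)
    p_exact <- mann_whitney_u(x, y, method = "exact")$p_two_sided
    expect_equal(p_exact, p_enum, tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(c(1, 1, 2), c(2, 3), method = "exact"), "tie")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})
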