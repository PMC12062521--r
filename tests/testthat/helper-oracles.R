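# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force CLSI percentile: sort, rank r = p(n+1), linear interpolation
oracle_percentile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  r <- p * (n + 1)
  if (r <= 1) return(s[1])
  if (r >= n) return(s[n])
  f <- r - floor(r)
  s[floor(r)] * (1 - f) + s[floor(r) + 1] * f
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n_x + n_y, n_x) group assignments (tie-free samples only)
oracle_mw_exact_p <- function(x, y) {
  v <- c(x, y)
  stopifnot(!any(duplicated(v)))
  nx <- length(x)
  r <- rank(v)
  idx <- utils::combn(length(v), nx)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  U_obs <- sum(outer(x, y, ">"))
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# a bccg_centile_fit object carrying the exact generating curves of a
# cohort_config: log mu is linear in age, sigma and nu constant
truth_model <- function(cfg, age_domain = c(20, 70)) {
  mk <- function(sex) {
    center <- mean(age_domain); scale <- 10
    mu_c <- cfg$mu_scale * 10^(cfg$mu_log10_slope * center) *
      if (sex == "F") cfg$female_mu_ratio else 1
    list(spec_mu = list(type = "linear", edf = 2L,
                        center = center, scale = scale),
         spec_sigma = list(type = "const", edf = 1L),
         spec_nu = list(type = "const", edf = 1L),
         coef_mu = c(log(mu_c), cfg$mu_log10_slope * log(10) * scale),
         coef_sigma = log(cfg$sigma), coef_nu = cfg$nu,
         loglik = NA_real_, iterations = 0L, converged = TRUE,
         edf = c(mu = 2L, sigma = 1L, nu = 1L), n = 0L,
         age_range = age_domain)
  }
  structure(list(strata = list(M = mk("M"), F = mk("F")), by_sex = TRUE,
                 age_domain = age_domain,
                 edf = c(mu = 2L, sigma = 1L, nu = 1L),
                 data = NULL, call = NULL),
            class = "bccg_centile_fit")
}

# cohort CSV fixture writer
write_cohort_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("subject_id,age_years,sex,snfl_pg_ml", lines), path)
  path
}
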