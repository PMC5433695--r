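test_that("squared phenotype differences are 0/1 for binary traits", {
  expect_equal(squared_phenotype_difference(1, 1), 0L)
  expect_equal(squared_phenotype_difference(1, 0), 1L)
  expect_equal(squared_phenotype_difference(0, 0), 0L)
  expect_equal(squared_phenotype_difference(c(1, 1, 0), c(1, 0, 0)),
               c(0L, 1L, 0L))
  expect_error(squared_phenotype_difference(2, 0), "0 or 1")
})

test_that("Haseman-Elston OLS matches the closed form on the 3-point design", {
  d <- make_pairs(c(1, 1, 1), c(0, 1, 1), c(0.4, 0.5, 0.6),
                  sq_diff = c(1, 0.5, 0))
  fit <- fit_he_ols(d)
  expect_equal(fit$beta, -5)
  expect_equal(fit$alpha, 3)
  # flat response: zero slope
  flat <- make_pairs(c(1, 1, 1), c(0, 0, 0), c(0.4, 0.5, 0.6))
  expect_equal(fit_he_ols(flat)$beta, 0)
})

test_that("OLS agrees with a brute-force normal-equations oracle to 1e-10", {
  set.seed(7)
  for (n in c(10, 50, 200)) {
    d <- make_pairs(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
                    runif(n, 0.3, 0.7))
    fit <- fit_he_ols(d)
    ref <- ols_oracle(d$pi_hat, he_response_oracle(d))
    expect_equal(fit$alpha, ref[1], tolerance = 1e-10)
    expect_equal(fit$beta, ref[2], tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_he_ols(make_pairs(c(1, 0), c(0, 0), c(0.5, 0.5))),
               "at least 3")
  expect_error(fit_he_ols(make_pairs(c(1, 0, 1), c(0, 0, 0), rep(0.5, 3))),
               "zero variance")
})

test_that("mixed model collapses to OLS without between-region signal", {
  d <- make_pairs(rep(1, 40), rep(c(0, 1), 20),
                  seq(0.3, 0.7, length.out = 40),
                  region = rep("R1", 40))
  expect_message(fit1 <- fit_he_mixed(d), "single region")
  expect_equal(fit1$beta, fit_he_ols(d)$beta, tolerance = 1e-8)
  expect_equal(fit1$region_variance, 0)

  # two regions with identical within-region data: no between-region variance
  d2 <- rbind(d, d)
  d2$region <- rep(c("R1", "R2"), each = 40)
  class(d2) <- class(d)
  fit2 <- fit_he_mixed(d2)
  expect_equal(fit2$beta, fit_he_ols(d2)$beta, tolerance = 1e-6)
  expect_lt(fit2$region_variance, 1e-8)
})

test_that("mixed model recovers a generating slope under region shifts", {
  set.seed(11)
  n <- 2000
  region <- sample(paste0("R", 1:4), n, replace = TRUE)
  shift <- c(R1 = 0.1, R2 = -0.1, R3 = 0.1, R4 = -0.1)[region]
  x <- rnorm(n, 0.5, 0.056)
  y <- 3 - 5 * x + shift + rnorm(n, 0, 0.3)
  d <- make_pairs(rep(1, n), rep(0, n), x, region = region, sq_diff = y)
  fit <- fit_he_mixed(d)
  mc_se <- 0.3 / (0.056 * sqrt(n))
  expect_lt(abs(fit$beta - (-5)), 2 * mc_se)
  expect_gt(fit$region_variance, 0)
})

test_that("observed-scale heritability follows -beta / (2 var_p)", {
  expect_equal(observed_h2(-0.5, 0.25), 1)
  expect_equal(observed_h2(0, 0.25), 0)
  expect_equal(observed_h2(-0.25, 0.25), 0.5)
  expect_warning(h <- observed_h2(0.1, 0.25), "negative")
  expect_equal(h, -0.2)
  expect_error(observed_h2(-0.5, 0), "positive")
})

test_that("binary phenotypic variance is Bernoulli and maximal at 0.5", {
  expect_equal(phenotypic_variance(0.5), 0.25)
  expect_equal(phenotypic_variance(0.1), 0.09)
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_equal(ps[which.max(phenotypic_variance(ps))], 0.5)
  expect_error(phenotypic_variance(1), "\\(0, 1\\)")
})

test_that("liability multiplier has its closed forms and K-monotonicity", {
  m <- liability_multiplier(0.5, 0.5)
  expect_equal(m$multiplier, pi / 2, tolerance = 1e-12)
  expect_equal(m$threshold_t, 0)
  expect_equal(m$density_z, 1 / sqrt(2 * pi), tolerance = 1e-12)

  # K = 0.01, P = 0.5: frozen from an independent quantile/density route
  l <- liability_scale(1, 0.01, 0.5)
  expect_equal(l$h2_liability, 0.5519073, tolerance = 1e-6)
  expect_equal(l$threshold_t, stats::qnorm(0.99), tolerance = 1e-9)
  expect_equal(l$density_z, exp(-l$threshold_t^2 / 2) / sqrt(2 * pi),
               tolerance = 1e-12)

  expect_equal(liability_scale(0, 0.2, 0.3)$h2_liability, 0)

  ks <- c(0.003, 0.005, 0.01, 0.03, 0.1, 0.3, 0.5)
  mult <- vapply(ks, function(k) liability_multiplier(k, 0.5)$multiplier,
                 numeric(1))
  expect_true(all(diff(mult) > 0))
})

test_that("liability-scale h2 is strictly increasing in -beta at fixed K, P", {
  betas <- seq(-1, 0.5, by = 0.1)
  h2l <- vapply(betas, function(b)
    liability_scale(observed_h2_quiet(b, 0.25), 0.01, 0.5)$h2_liability,
    numeric(1))
  expect_true(all(diff(h2l) < 0))  # increasing beta = decreasing -beta
})

test_that("stratified bootstrap is deterministic under a fixed seed", {
  st <- null_strata()
  a <- bootstrap_h2(st, prevalence_k = 0.01, n_per_stratum = 50,
                    replicates = 200, seed = 123)
  b <- bootstrap_h2(st, prevalence_k = 0.01, n_per_stratum = 50,
                    replicates = 200, seed = 123)
  expect_identical(a$h2_liability, b$h2_liability)
  expect_identical(a$se, b$se)
  expect_identical(a$replicates, b$replicates)
})

test_that("bootstrap under a zero-slope population centres on zero", {
  st <- null_strata(n = 300, seed = 5)
  est <- bootstrap_h2(st, prevalence_k = 0.01, n_per_stratum = 300,
                      replicates = 500, seed = 42)
  expect_lt(abs(est$h2_liability), 3 * est$se)
  expect_gte(est$se, 0)
  expect_equal(est$case_proportion_p, 0.5)
  expect_equal(est$n_replicates, 500)
})

test_that("bootstrap validates its strata", {
  st <- null_strata()
  st$AU <- st$AU[0, ]
  expect_error(bootstrap_h2(st, 0.01, replicates = 10, seed = 1),
               "empty stratum: AU")
})

test_that("the report shares slopes across prevalences and is K-monotone", {
  st <- null_strata(n = 200, seed = 31)
  # inject a genuine negative slope: lower sharing in the discordant stratum
  st$AU$pi_hat <- st$AU$pi_hat - 0.03
  rep <- heritability_report(st, c(0.003, 0.005, 0.01, 0.03),
                             n_per_stratum = 100, replicates = 300, seed = 8)
  expect_equal(nrow(rep), 4)
  expect_true(all(diff(rep$h2_liability) > 0))
  expect_equal(length(unique(rep$h2_observed)), 1)  # same slopes, new K only
  expect_true(all(rep$se >= 0))
  expect_equal(rep$se_of_mean, rep$se / sqrt(rep$n_replicates))
})

test_that("IBD normality diagnostics report moments of a normal sample", {
  set.seed(2)
  d <- ibd_normality_diagnostics(rnorm(20000, 0.5, 0.05))
  expect_equal(d$mean, 0.5, tolerance = 0.005)
  expect_lt(abs(d$skewness), 0.05)
  expect_lt(abs(d$excess_kurtosis), 0.1)
})
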