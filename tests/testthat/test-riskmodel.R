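test_that("the 9-feature vector encodes dosages and match indicators", {
  f <- build_features(matrix(c(0, 1, 2), 1), matrix(c(0, 1, 2), 1))
  expect_equal(drop(f), setNames(c(0, 1, 2, 0, 1, 2, 1, 1, 1), paste0("g", 1:9)))
  f2 <- build_features(matrix(c(0, 1, 2), 1), matrix(c(2, 1, 0), 1))
  expect_equal(unname(drop(f2)), c(0, 1, 2, 2, 1, 0, 0, 1, 0))
  f3 <- build_features(matrix(c(2, 2, 2), 1), matrix(c(0, 0, 0), 1))
  expect_equal(unname(drop(f3)[7:9]), c(0, 0, 0))
  # indicators always consistent with dosage equality
  set.seed(3)
  gp <- matrix(sample(0:2, 60, TRUE), ncol = 3)
  gs <- matrix(sample(0:2, 60, TRUE), ncol = 3)
  ff <- build_features(gp, gs)
  expect_equal(unname(ff[, 7:9]), unname((gp == gs) + 0))
  expect_true(all(ff[, 7:9] %in% c(0, 1)))
})

test_that("missing or invalid dosages are rejected with guidance", {
  expect_error(build_features(matrix(c(NA, 1, 2), 1), matrix(c(0, 1, 2), 1)),
               "drop_incomplete_genotypes")
  expect_error(build_features(matrix(c(3, 1, 2), 1), matrix(c(0, 1, 2), 1)),
               "0, 1 or 2")
  expect_error(build_features(matrix(0, 1, 2), matrix(0, 1, 3)), "3 SNP")
})

test_that("categorical coding expands dosages into dummies", {
  f <- build_features(matrix(c(0, 1, 2), 1), matrix(c(2, 1, 0), 1),
                      coding = "categorical")
  expect_equal(ncol(f), 15)
  expect_equal(unname(f[, "p2_het"]), 1)
  expect_equal(unname(f[, "p3_hom"]), 1)
  expect_equal(unname(f[, "s1_hom"]), 1)
})

test_that("drop_incomplete_genotypes drops and reports", {
  p <- make_pairs(c(1, 1), c(0, 0), c(0.5, 0.5))
  p[, sibscreen:::.snp_cols] <- 1
  p$snp2_s[2] <- NA
  expect_message(out <- drop_incomplete_genotypes(p), "dropped 1")
  expect_equal(nrow(out), 1)
})

test_that("intercept-only logistic data give the closed-form intercept", {
  y <- c(rep(1, 30), rep(0, 70))
  X <- matrix(1, 100, 1, dimnames = list(NULL, "const"))
  fit <- fit_logistic(X, y)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(0.3 / 0.7),
               tolerance = 1e-8)
  expect_equal(fit$dropped, "const")  # constant feature excluded
  expect_true(fit$converged)
})

test_that("IRLS coefficients match the glm maximum-likelihood oracle to 1e-5", {
  set.seed(19)
  n <- 200
  gp <- matrix(rbinom(3 * n, 2, 0.3), ncol = 3)
  gs <- matrix(rbinom(3 * n, 2, 0.3), ncol = 3)
  X <- build_features(gp, gs)
  eta <- -1 + 0.8 * X[, 1] - 0.5 * X[, 4] + 0.3 * X[, 7]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(X, y)
  oracle <- glm.fit(cbind(1, X), y, family = binomial())
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-5)
  # score equation identity: fitted probabilities sum to the case count
  expect_lt(abs(sum(fit$fitted) - sum(y)), 1e-6)
})

test_that("permuted labels give slope coefficients near zero", {
  set.seed(23)
  n <- 400
  gp <- matrix(rbinom(3 * n, 2, 0.4), ncol = 3)
  gs <- matrix(rbinom(3 * n, 2, 0.4), ncol = 3)
  X <- build_features(gp, gs)
  y <- sample(rep(c(0, 1), each = n / 2))   # independent of X
  fit <- fit_logistic(X, y)
  z <- fit$coefficients[-1] / fit$se[-1]
  expect_true(all(abs(z) < 3))
})

test_that("degenerate logistic inputs are rejected", {
  X <- matrix(rnorm(20), ncol = 1, dimnames = list(NULL, "x"))
  expect_error(fit_logistic(X, rep(1, 20)), "single class")
  # complete separation
  Xs <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1, dimnames = list(NULL, "x"))
  ys <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(Xs, ys), "separation")
  fit <- fit_logistic(Xs, ys, ridge = 0.5)  # ridge fallback works
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("risk scores follow the linear predictor and logistic link", {
  X <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "g"))
  model <- structure(list(coefficients = c(`(Intercept)` = 0, g = 0)),
                     class = "sib_logit")
  pr <- predict_risk(model, X)
  expect_equal(pr$probability, rep(0.5, 3))  # zero coefficients
  model$coefficients <- c(`(Intercept)` = 0, g = 1.2)
  pr2 <- predict_risk(model, X)
  expect_equal(pr2$logit, c(0, 1.2, 2.4))
  expect_true(all(diff(pr2$probability) > 0))  # monotone in the feature
  expect_equal(pr2$probability[1], 0.5)        # logit 0 -> 0.5
})

test_that("discovery/validation split is stratified, sized and reproducible", {
  p <- make_pairs(rep(1, 1253), rep(c(0, 1), length.out = 1253),
                  runif(1253, 0.3, 0.7))
  s <- split_discovery_validation(p, 750 / 1253, seed = 4)
  expect_equal(nrow(s$discovery), 750)
  expect_equal(nrow(s$validation), 503)

  p2 <- make_pairs(rep(1, 100), rep(c(0, 1), 50), runif(100))
  s2 <- split_discovery_validation(p2, 0.5, seed = 9)
  expect_equal(sum(s2$discovery$pheno_sib), 25)
  expect_equal(sum(s2$validation$pheno_sib), 25)

  s3 <- split_discovery_validation(p2, 0.5, seed = 9)
  expect_identical(s2$discovery$pair_id, s3$discovery$pair_id)
  expect_error(split_discovery_validation(p2, 1.2, seed = 1), "\\(0, 1\\)")
})

test_that("ROC handles perfect separation, ties and the worked example", {
  r1 <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1)
  r2 <- roc_curve(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(r3$auc, 0.75)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC geometry: starts at (0,0), ends at (1,1), monotone", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- roc_curve(sc, y)
    expect_equal(unlist(r$points[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
    expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")],
                        use.names = FALSE), c(1, 1))
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }
})

test_that("AUC equals the brute-force count and is monotone-invariant", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(6:50, 1)
    sc <- round(rnorm(n), 1)                          # ties likely
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    r <- roc_curve(sc, y)
    expect_identical(r$auc, auc_oracle(sc, y))
    r_t <- roc_curve(exp(3 * sc) - 2, y)              # strictly monotone map
    expect_equal(r_t$auc, r$auc)
  }
})

test_that("AUC and Hanley-McNeil se agree with the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(77)
  sc <- rnorm(120)
  y <- rbinom(120, 1, plogis(sc))
  r <- roc_curve(sc, y)
  ref <- suppressMessages(pROC::auc(y, sc))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  expect_gt(r$se, 0)
  expect_true(r$ci95[1] >= 0 && r$ci95[2] <= 1 && r$ci95[1] <= r$ci95[2])
})

test_that("the DR3/4 single-indicator baseline behaves like a binary test", {
  set.seed(5)
  y <- rep(c(1, 0), 100)
  b1 <- suppressMessages(dr34_baseline(indicator = y, labels = y))  # indicator = phenotype
  expect_equal(b1$roc$auc, 1)
  b2 <- dr34_baseline(indicator = rbinom(200, 1, 0.5), labels = y)
  expect_lt(abs(b2$roc$auc - 0.5), 3 * b2$roc$se)     # independent indicator
  expect_equal(nrow(b2$roc$points), 3)                # binary test geometry
})

test_that("mirrored pair observations are balanced and oriented", {
  p <- make_pairs(c(1, 0, 1), c(0, 1, 1), c(0.5, 0.5, 0.5))
  p[, sibscreen:::.snp_cols] <- cbind(2, 1, 0, 0, 1, 2)[rep(1, 3), ]
  p$dr34_proband <- c(1, 0, 1); p$dr34_sib <- c(0, 1, 0)
  expect_message(obs <- pair_observations(p), "1 concordant")
  expect_equal(length(obs$labels), 4)          # 2 discordant pairs x 2 views
  expect_equal(mean(obs$labels), 0.5)          # balanced by construction
  # row 2 is sib-affected: orientation must flip genotypes and dr34
  expect_equal(unname(obs$features[2, 1:3]), c(0, 1, 2))
  expect_equal(obs$dr34, c(1, 1, 0, 0))
})

test_that("screening metrics follow Bayes' rule at any operating point", {
  m <- screening_metrics(1, 1, 0.1)
  expect_equal(c(m$ppv, m$npv), c(1, 1))
  m2 <- screening_metrics(0.3, 0.9, 0.01)
  expect_equal(m2$ppv, 0.003 / (0.003 + 0.099), tolerance = 1e-12)
  expect_equal(m2$npv, 0.9 * 0.99 / (0.7 * 0.01 + 0.9 * 0.99),
               tolerance = 1e-12)
  # Bayes identities hold to 1e-12 across a grid
  for (se in c(0.2, 0.5, 0.9)) for (sp in c(0.6, 0.95)) for (K in c(0.001, 0.03)) {
    mm <- screening_metrics(se, sp, K)
    expect_equal(mm$ppv, se * K / (se * K + (1 - sp) * (1 - K)),
                 tolerance = 1e-12)
  }
  # PPV -> 0 as prevalence vanishes with an imperfect test
  expect_lt(screening_metrics(0.8, 0.9, 1e-6)$ppv, 1e-4)
  # degenerate denominator
  d <- screening_metrics(0, 1, 0.5)
  expect_true(d$degenerate)
  expect_equal(d$ppv, 0)
})

test_that("operating point maximizes specificity above the sensitivity floor", {
  sc <- c(5, 4, 3, 2, 1, 0)
  y <- c(1, 1, 0, 1, 0, 0)
  r <- roc_curve(sc, y)
  op <- operating_point(r, min_sensitivity = 0.3)
  expect_gte(op$tpr, 0.3)
  ok <- r$points$tpr >= 0.3
  expect_equal(op$fpr, min(r$points$fpr[ok]))
  expect_error(operating_point(r, min_sensitivity = 1.5), "sensitivity")
})
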