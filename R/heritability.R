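# Haseman-Elston sib-pair heritability.
#
# The regression is of the squared phenotype difference (P_i1 - P_i2)^2 of
# sib pair i on the pair's genome-wide IBD proportion pi-hat:
#
#   (P_i1 - P_i2)^2 = alpha + beta * pi_hat (+ u_region)
#
# A negative slope indicates additive genetic variance; the observed-scale
# heritability is -beta / (2 * var_p), and for an ascertained case-control
# sample it is moved to the liability scale with the standard
# prevalence/threshold correction.

#' Squared sib-pair phenotype difference
#'
#' For a binary trait this is 0 for concordant and 1 for discordant pairs:
#' the Haseman-Elston response variable.
#'
#' @param p1,p2 Binary phenotype vectors (0/1).
#' @return `(p1 - p2)^2`, an integer vector.
#' @export
squared_phenotype_difference <- function(p1, p2) {
  if (any(!p1 %in% c(0, 1)) || any(!p2 %in% c(0, 1)))
    stop("phenotypes must be 0 or 1", call. = FALSE)
  as.integer((p1 - p2)^2)
}

#' Haseman-Elston regression by ordinary least squares
#'
#' Regresses the squared phenotype difference on \eqn{\hat\pi} and returns
#' the intercept and slope.  Fitting goes through the QR decomposition
#' (`stats::lm.fit`).
#'
#' @param pairs A `sib_pairs` data frame with `pheno_proband`, `pheno_sib`
#'   and `pi_hat` columns.
#' @return An object of class `"he_fit"`: list with `alpha`, `beta`,
#'   `n_pairs`, `method = "ols"`, `region_variance = NA`.
#' @examples
#' d <- data.frame(pheno_proband = c(1, 1, 1), pheno_sib = c(0, 1, 1),
#'                 pi_hat = c(0.4, 0.5, 0.6))
#' fit_he_ols(d)  # discordance falls with sharing: beta < 0
#' @export
fit_he_ols <- function(pairs) {
  x <- pairs$pi_hat
  y <- he_response(pairs)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x)) stop("pi_hat contains missing values", call. = FALSE)
  if (stats::var(x) <= .Machine$double.eps)
    stop("degenerate design: pi_hat has zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(alpha = unname(fit$coefficients[1]),
                 beta = unname(fit$coefficients[2]),
                 n_pairs = length(x), method = "ols",
                 region_variance = NA_real_),
            class = "he_fit")
}

# response used by both fitters; tolerates a precomputed sq_diff column
he_response <- function(pairs) {
  if (!is.null(pairs$sq_diff)) return(pairs$sq_diff)
  squared_phenotype_difference(pairs$pheno_proband, pairs$pheno_sib)
}

#' Haseman-Elston regression with a region random intercept
#'
#' Fits `(P1 - P2)^2 ~ pi_hat + (1 | region)` by REML through
#' \pkg{lme4}, to absorb between-region stratification in cohorts drawn
#' from multiple populations.  With a single region (or on
#' non-convergence) it falls back to [fit_he_ols()] with
#' `region_variance = 0` and a message.
#'
#' @param pairs A `sib_pairs` data frame with a `region` column.
#' @return An `"he_fit"` with `method = "mixed"` and the estimated
#'   between-region intercept variance.
#' @export
fit_he_mixed <- function(pairs) {
  if (is.null(pairs$region))
    stop("fit_he_mixed needs a 'region' column", call. = FALSE)
  regions <- unique(pairs$region)
  if (length(regions) < 2L) {
    message("single region: falling back to OLS")
    fit <- fit_he_ols(pairs)
    fit$region_variance <- 0
    return(fit)
  }
  d <- data.frame(y = he_response(pairs), pi_hat = pairs$pi_hat,
                  region = factor(pairs$region))
  fit <- tryCatch(
    lme4::lmer(y ~ pi_hat + (1 | region), data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) NULL)
  if (is.null(fit)) {
    message("mixed model did not converge: falling back to OLS")
    out <- fit_he_ols(pairs)
    out$region_variance <- 0
    return(out)
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(alpha = unname(fe[1]), beta = unname(fe[2]),
                 n_pairs = nrow(d), method = "mixed",
                 region_variance = vc$vcov[vc$grp == "region"][1]),
            class = "he_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf("Haseman-Elston fit (%s), %d pairs\n", x$method, x$n_pairs))
  cat(sprintf("  alpha = %.4f, beta = %.4f", x$alpha, x$beta))
  if (x$method == "mixed")
    cat(sprintf(", region variance = %.4g", x$region_variance))
  cat("\n")
  invisible(x)
}

#' Phenotypic variance of a binary trait
#'
#' For a 0/1 trait with case proportion \eqn{P} the phenotypic variance is
#' the Bernoulli variance \eqn{P(1-P)}.
#'
#' @param case_proportion_p Case proportion in (0, 1).
#' @return `P * (1 - P)`.
#' @export
phenotypic_variance <- function(case_proportion_p) {
  p <- case_proportion_p
  if (any(p <= 0 | p >= 1))
    stop("case proportion must lie strictly inside (0, 1)", call. = FALSE)
  p * (1 - p)
}

#' Observed-scale heritability from the Haseman-Elston slope
#'
#' \eqn{\hat h^2_o = -\hat\beta / (2 \hat\sigma^2_p)}.  Estimates are
#' returned as-is (a positive slope gives a negative estimate, with a
#' warning): clamping would bias bootstrap distributions.
#'
#' @param beta Haseman-Elston slope.
#' @param var_p Phenotypic variance (> 0).
#' @return Observed-scale heritability estimate.
#' @export
observed_h2 <- function(beta, var_p) {
  if (any(var_p <= 0)) stop("phenotypic variance must be positive", call. = FALSE)
  h2 <- -beta / (2 * var_p)
  if (any(h2 < 0)) warning("negative heritability estimate (positive HE slope)",
                           call. = FALSE)
  h2
}

#' Observed-to-liability scale multiplier
#'
#' The factor that converts an observed-scale case-control heritability to
#' the liability scale:
#' \deqn{m(K, P) = \frac{K(1-K)}{z^2}\,\frac{K(1-K)}{P(1-P)}}
#' with truncation threshold \eqn{T = \Phi^{-1}(1-K)} and \eqn{z = \phi(T)}
#' the standard normal density at the threshold.  At \eqn{K = P = 0.5} the
#' multiplier is \eqn{\pi/2}; for fixed \eqn{P} it increases with \eqn{K}
#' on (0, 0.5].
#'
#' @param prevalence_k Population prevalence \eqn{K} in (0, 1).
#' @param case_proportion_p Sample case proportion \eqn{P} in (0, 1).
#' @return List with `multiplier`, `threshold_t`, `density_z`.
#' @export
liability_multiplier <- function(prevalence_k, case_proportion_p) {
  K <- prevalence_k; P <- case_proportion_p
  if (any(K <= 0 | K >= 1)) stop("prevalence K must be in (0, 1)", call. = FALSE)
  if (any(P <= 0 | P >= 1)) stop("case proportion P must be in (0, 1)", call. = FALSE)
  T <- stats::qnorm(1 - K)
  z <- exp(-T^2 / 2) / sqrt(2 * pi)
  list(multiplier = (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P))),
       threshold_t = T, density_z = z)
}

#' Transform observed-scale heritability to the liability scale
#'
#' @param h2_observed Observed-scale estimate.
#' @inheritParams liability_multiplier
#' @return List with `h2_liability`, `threshold_t`, `density_z`,
#'   `multiplier`.
#' @export
liability_scale <- function(h2_observed, prevalence_k, case_proportion_p) {
  m <- liability_multiplier(prevalence_k, case_proportion_p)
  c(list(h2_liability = h2_observed * m$multiplier), m)
}

# -- stratified bootstrap ----------------------------------------------------

#' Stratified bootstrap of the Haseman-Elston slope
#'
#' Workhorse behind [bootstrap_h2()].  Each replicate draws
#' `n_per_stratum` pairs with replacement from each of the
#' affected-affected, discordant and unaffected-unaffected strata,
#' refits the Haseman-Elston regression on the pooled draw, and records
#' the slope.  With three equal strata the rebuilt dataset has case
#' proportion 0.5 by construction.
#'
#' @param strata Named list of `sib_pairs` data frames: `AA`, `AU`, `UU`.
#' @param n_per_stratum Pairs drawn per stratum per replicate.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed; the draw sequence is fully determined by it.
#' @param use_regions Use [fit_he_mixed()] when all strata carry regions.
#' @return List with `beta` (replicate slopes, skipped replicates removed),
#'   `n_skipped`, `case_proportion_p`.
#' @export
bootstrap_he_slopes <- function(strata, n_per_stratum = 300,
                                replicates = 10000, seed = 1,
                                use_regions = FALSE) {
  stopifnot(is.list(strata), all(c("AA", "AU", "UU") %in% names(strata)))
  for (s in c("AA", "AU", "UU"))
    if (is.null(strata[[s]]) || nrow(strata[[s]]) == 0L)
      stop(sprintf("empty stratum: %s", s), call. = FALSE)
  has_regions <- use_regions &&
    all(vapply(strata, function(d) !is.null(d$region), logical(1)))
  # precompute responses once; resampling only permutes rows
  xs <- lapply(strata, function(d) d$pi_hat)
  ys <- lapply(strata, function(d) he_response(d))
  rg <- if (has_regions) lapply(strata, function(d) d$region)
  ns <- vapply(xs, length, integer(1))
  set.seed(seed)
  beta <- rep(NA_real_, replicates)
  n_skip <- 0L
  for (b in seq_len(replicates)) {
    idx <- lapply(ns, function(n) sample.int(n, n_per_stratum, replace = TRUE))
    x <- c(xs$AA[idx$AA], xs$AU[idx$AU], xs$UU[idx$UU])
    if (stats::var(x) <= .Machine$double.eps) { n_skip <- n_skip + 1L; next }
    y <- c(ys$AA[idx$AA], ys$AU[idx$AU], ys$UU[idx$UU])
    if (has_regions) {
      d <- data.frame(pi_hat = x, sq_diff = y,
                      region = c(rg$AA[idx$AA], rg$AU[idx$AU], rg$UU[idx$UU]))
      beta[b] <- suppressMessages(fit_he_mixed(d)$beta)
    } else {
      # closed-form OLS slope: cov(x, y) / var(x)
      beta[b] <- stats::cov(x, y) / stats::var(x)
    }
  }
  if (n_skip > 0.01 * replicates)
    stop(sprintf("%d of %d replicates had degenerate pi_hat", n_skip, replicates),
         call. = FALSE)
  list(beta = beta[!is.na(beta)], n_skipped = n_skip,
       case_proportion_p = 0.5)
}

#' Bootstrap heritability estimate with liability-scale transformation
#'
#' Runs the stratified bootstrap of the Haseman-Elston slope, converts each
#' replicate slope to observed-scale heritability with
#' \eqn{\hat\sigma^2_p = P(1-P)} (P = 0.5 under the balanced design, so
#' 0.25), transforms to the liability scale at prevalence `prevalence_k`,
#' and summarises the replicate distribution.
#'
#' @inheritParams bootstrap_he_slopes
#' @param prevalence_k Population prevalence \eqn{K}.
#' @param slopes Optional precomputed result of [bootstrap_he_slopes()];
#'   lets several prevalence settings reuse one set of replicates.
#' @return An object of class `"heritability_estimate"`: point estimate
#'   (`h2_liability`, the replicate mean), `se` (replicate standard
#'   deviation), `se_of_mean` (`se / sqrt(B)`), `h2_observed`, the
#'   `K`/`P`/`T`/`z` used, counts, and the replicate vector in
#'   `$replicates`.
#' @export
bootstrap_h2 <- function(strata, prevalence_k, n_per_stratum = 300,
                         replicates = 10000, seed = 1, use_regions = FALSE,
                         slopes = NULL) {
  if (is.null(slopes))
    slopes <- bootstrap_he_slopes(strata, n_per_stratum = n_per_stratum,
                                  replicates = replicates, seed = seed,
                                  use_regions = use_regions)
  P <- slopes$case_proportion_p
  var_p <- phenotypic_variance(P)
  h2o <- suppressWarnings(observed_h2(slopes$beta, var_p))
  m <- liability_multiplier(prevalence_k, P)
  h2l <- h2o * m$multiplier
  B <- length(h2l)
  structure(list(h2_liability = mean(h2l), se = stats::sd(h2l),
                 se_of_mean = stats::sd(h2l) / sqrt(B),
                 h2_observed = mean(h2o),
                 beta = mean(slopes$beta),
                 prevalence_k = prevalence_k, case_proportion_p = P,
                 threshold_t = m$threshold_t, density_z = m$density_z,
                 n_per_stratum = n_per_stratum, n_replicates = B,
                 n_skipped = slopes$n_skipped, seed = seed,
                 replicates = h2l),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Liability-scale heritability at K = %g\n", x$prevalence_k))
  cat(sprintf("  h2_L = %.3f (se %.4g, se of mean %.4g)\n",
              x$h2_liability, x$se, x$se_of_mean))
  cat(sprintf("  h2_observed = %.3f, mean HE slope = %.4f\n",
              x$h2_observed, x$beta))
  cat(sprintf("  %d replicates of 3 x %d pairs, P = %g, seed %d\n",
              x$n_replicates, x$n_per_stratum, x$case_proportion_p,
              as.integer(x$seed)))
  invisible(x)
}

#' Split a pair table into concordance strata
#'
#' @param pairs A `sib_pairs` data frame.
#' @return Named list of data frames `AA`, `AU`, `UU`.
#' @export
split_strata <- function(pairs) {
  cls <- pair_class(pairs)
  lapply(stats::setNames(levels(cls), levels(cls)),
         function(l) pairs[cls == l, , drop = FALSE])
}

#' Heritability report across prevalence settings
#'
#' Runs one stratified bootstrap and reports the liability-scale estimate
#' at each prevalence in `prevalences` (the replicate slopes are shared:
#' only the liability multiplier changes with K).
#'
#' @inheritParams bootstrap_h2
#' @param prevalences Vector of prevalence settings K.
#' @return Data frame with one row per K: `prevalence_k`, `h2_observed`,
#'   `h2_liability`, `se`, `se_of_mean`, `n_replicates`, `seed`.
#' @export
heritability_report <- function(strata, prevalences, n_per_stratum = 300,
                                replicates = 10000, seed = 1,
                                use_regions = FALSE) {
  if (length(prevalences) == 0L)
    stop("at least one prevalence setting is required", call. = FALSE)
  slopes <- bootstrap_he_slopes(strata, n_per_stratum = n_per_stratum,
                                replicates = replicates, seed = seed,
                                use_regions = use_regions)
  rows <- lapply(prevalences, function(K) {
    est <- bootstrap_h2(strata, K, slopes = slopes, seed = seed,
                        n_per_stratum = n_per_stratum)
    data.frame(prevalence_k = K, h2_observed = est$h2_observed,
               h2_liability = est$h2_liability, se = est$se,
               se_of_mean = est$se_of_mean, n_replicates = est$n_replicates,
               seed = as.integer(seed))
  })
  do.call(rbind, rows)
}

#' Normality diagnostics for the IBD distribution
#'
#' Skewness and excess kurtosis of \eqn{\hat\pi}: a diagnostic (never a
#' gate) for the approximate normality the regression assumes genome-wide.
#'
#' @param pi_hat Numeric vector of IBD proportions.
#' @return List with `mean`, `sd`, `skewness`, `excess_kurtosis`, `n`.
#' @export
ibd_normality_diagnostics <- function(pi_hat) {
  x <- pi_hat[!is.na(pi_hat)]
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  z <- (x - m) / s
  list(mean = m, sd = s, skewness = mean(z^3),
       excess_kurtosis = mean(z^4) - 3, n = n)
}
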