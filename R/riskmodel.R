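# Sib-pair SNP risk model.
#
# The predictor for one proband-sib pair is a 9-dimensional vector: the
# three SNP allele dosages of the proband, the three dosages of the sib,
# and three binary indicators of whether proband and sib carry the same
# genotype at each SNP.  A logistic regression of the sib's disease status
# on these features gives a per-pair risk score; discrimination is read
# off the ROC curve.

#' Build the 9-dimensional sib-pair feature matrix
#'
#' Features `g1..g3` are the proband's allele dosages at the three SNPs,
#' `g4..g6` the sib's, and `g7..g9` indicate genotype equality at each SNP.
#' Dosages are additive 0/1/2 by default; `coding = "categorical"` expands
#' each dosage into two dummy columns (heterozygote, risk homozygote) for
#' sensitivity analysis.
#'
#' @param proband,sib Numeric matrices (n x 3) of allele dosages in
#'   \{0, 1, 2\}; no missing values (drop or impute upstream — see
#'   [drop_incomplete_genotypes()]).
#' @param coding `"additive"` (default) or `"categorical"`.
#' @return Numeric feature matrix with n rows; 9 columns `g1..g9` for
#'   additive coding, 15 for categorical (12 dummies + 3 indicators).
#' @export
build_features <- function(proband, sib, coding = c("additive", "categorical")) {
  coding <- match.arg(coding)
  proband <- as.matrix(proband); sib <- as.matrix(sib)
  if (ncol(proband) != 3L || ncol(sib) != 3L)
    stop("expected 3 SNP dosage columns for proband and sib", call. = FALSE)
  if (anyNA(proband) || anyNA(sib))
    stop("missing genotype dosages: drop incomplete pairs first (see drop_incomplete_genotypes)",
         call. = FALSE)
  if (!all(proband %in% c(0, 1, 2)) || !all(sib %in% c(0, 1, 2)))
    stop("allele dosages must be 0, 1 or 2", call. = FALSE)
  match_ind <- (proband == sib) + 0
  if (coding == "additive") {
    out <- cbind(proband, sib, match_ind)
    colnames(out) <- paste0("g", 1:9)
  } else {
    dummies <- function(m, tag)
      do.call(cbind, lapply(1:3, function(j) {
        d <- cbind((m[, j] == 1) + 0, (m[, j] == 2) + 0)
        colnames(d) <- paste0(tag, j, c("_het", "_hom"))
        d
      }))
    out <- cbind(dummies(proband, "p"), dummies(sib, "s"), match_ind)
    colnames(out)[(ncol(out) - 2):ncol(out)] <- paste0("match", 1:3)
  }
  out
}

#' Drop pairs with incomplete genotypes
#'
#' @param pairs A `sib_pairs` data frame carrying the six dosage columns.
#' @return `pairs` without rows containing missing dosages; the number
#'   dropped is reported with a message when positive.
#' @export
drop_incomplete_genotypes <- function(pairs) {
  cols <- intersect(.snp_cols, names(pairs))
  if (length(cols) != 6L)
    stop("pair table lacks the six genotype columns", call. = FALSE)
  keep <- stats::complete.cases(pairs[, cols])
  if (any(!keep))
    message(sprintf("dropped %d pair(s) with missing genotypes", sum(!keep)))
  pairs[keep, , drop = FALSE]
}

#' Mirrored per-individual observations from discordant pairs
#'
#' The classification unit of the risk analysis is the individual, not the
#' pair: each affected-proband/unaffected-sib pair yields two mirrored
#' observations — the proband scored against the sib's genotypes (label 1)
#' and the sib scored against the proband's (label 0) — so every pair
#' contributes one case and one control and the design is balanced by
#' construction.  Concordant pairs are excluded (with a message); pairs
#' where the sib rather than the proband is affected are re-oriented.
#'
#' @param pairs A `sib_pairs` data frame with genotype columns and (for
#'   baselines) optional `dr34_proband`/`dr34_sib` flags.
#' @param coding Passed to [build_features()].
#' @return List: `features` (2n x 9 matrix), `labels` (2n), `pair_index`
#'   (2n, row of `pairs` each observation came from), `dr34` (2n focal
#'   indicator, or `NULL`).
#' @export
pair_observations <- function(pairs, coding = "additive") {
  disc <- pairs$pheno_proband != pairs$pheno_sib
  if (any(!disc))
    message(sprintf("excluded %d concordant pair(s) from the risk analysis",
                    sum(!disc)))
  d <- pairs[disc, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no discordant pairs: the risk analysis needs affected/unaffected pairs",
         call. = FALSE)
  flip <- d$pheno_sib == 1L   # orient: affected member is the proband
  g <- pair_genotypes(d)
  ga <- g$proband; gu <- g$sib
  ga[flip, ] <- g$sib[flip, ]; gu[flip, ] <- g$proband[flip, ]
  features <- rbind(build_features(ga, gu, coding = coding),
                    build_features(gu, ga, coding = coding))
  labels <- rep(c(1L, 0L), each = nrow(d))
  dr34 <- NULL
  if (!is.null(d$dr34_proband) && !is.null(d$dr34_sib)) {
    da <- ifelse(flip, d$dr34_sib, d$dr34_proband)
    du <- ifelse(flip, d$dr34_proband, d$dr34_sib)
    dr34 <- c(da, du)
  }
  list(features = features, labels = labels,
       pair_index = rep(which(disc), 2), dr34 = dr34)
}

#' Genotype matrices from a pair table
#'
#' @param pairs A `sib_pairs` data frame with genotype columns.
#' @return List with `proband` and `sib` n x 3 dosage matrices.
#' @export
pair_genotypes <- function(pairs) {
  list(proband = as.matrix(pairs[, c("snp1_p", "snp2_p", "snp3_p")]),
       sib = as.matrix(pairs[, c("snp1_s", "snp2_s", "snp3_s")]))
}

#' Fit a logistic risk model by maximum likelihood
#'
#' Iteratively reweighted least squares for the binomial log-likelihood of
#' \deqn{\mathrm{logit}\, \Pr(P = 1 \mid G) = B_0 + B_1 g_1 + \dots + B_n g_n.}
#' Convergence is declared when the log-likelihood changes by less than
#' `tolerance` and the score (gradient) has maximum absolute component
#' below `1e-6`.  Complete separation is reported as an error unless
#' `ridge > 0` adds an L2 penalty.
#'
#' @param features Numeric model matrix (no intercept column).
#' @param labels Binary response vector.
#' @param tolerance Convergence bound on the log-likelihood change.
#' @param max_iterations IRLS iteration cap.
#' @param ridge Optional L2 penalty (default 0 = plain ML).
#' @return Object of class `"sib_logit"`: `coefficients` (named, with
#'   `(Intercept)` first), `se`, `loglik`, `converged`, `n_iterations`,
#'   `fitted`, `n`.
#' @export
fit_logistic <- function(features, labels, tolerance = 1e-8,
                         max_iterations = 100, ridge = 0) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; cannot fit", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  # drop constant (non-intercept) columns: inestimable
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(v) stats::var(v) > 0))
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  p_col <- ncol(X)
  penalty <- ridge * diag(c(0, rep(1, p_col - 1)), nrow = p_col, ncol = p_col)
  beta <- numeric(p_col)
  beta[1] <- stats::qlogis(mean(y))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta))) - ridge * sum(b[-1]^2) / 2
  }
  score <- function(b)
    drop(crossprod(X, y - stats::plogis(drop(X %*% b)))) - ridge * c(0, b[-1])
  ll_old <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * sqrt(w)) + penalty
    step <- tryCatch(solve(H, score(beta)), error = function(e)
      stop("singular information matrix (collinear features?)", call. = FALSE))
    # step-halving to guarantee ascent
    s <- 1
    repeat {
      beta_new <- beta + s * step
      ll_new <- loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      s <- s / 2
      if (s < 1e-8) { ll_new <- ll_old; beta_new <- beta; break }
    }
    beta <- beta_new
    delta <- abs(ll_new - ll_old)
    ll_old <- ll_new
    if (delta < tolerance && max(abs(score(beta))) < 1e-6) {
      converged <- TRUE
      break
    }
    if (iter >= max_iterations) break
  }
  if (ridge == 0 && max(abs(beta)) > 15)
    stop("apparent complete separation: coefficients diverging; consider ridge > 0",
         call. = FALSE)
  if (!converged)
    warning(sprintf("IRLS did not converge in %d iterations", iter),
            call. = FALSE)
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  se <- sqrt(diag(solve(crossprod(X * sqrt(w)) + penalty)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 dropped = dropped, loglik = ll_old,
                 converged = converged, n_iterations = iter,
                 fitted = mu, n = length(y)),
            class = "sib_logit")
}

#' @export
print.sib_logit <- function(x, ...) {
  cat(sprintf("Sib-pair logistic model (%d obs, logLik %.3f, %s in %d iter)\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Score pairs with a fitted risk model
#'
#' @param model A `"sib_logit"` fit.
#' @param features Feature matrix with the columns the model was fit on.
#' @return Data frame with `logit` (risk score \eqn{B_0 + \sum B_i g_i})
#'   and `probability`.
#' @export
predict_risk <- function(model, features) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  X <- X[, names(model$coefficients), drop = FALSE]
  logit <- drop(X %*% model$coefficients)
  data.frame(logit = logit, probability = stats::plogis(logit))
}

#' Stratified discovery/validation split
#'
#' Randomly partitions pairs into a discovery and a validation set,
#' stratified by the sib's phenotype so the case:control proportion is
#' equal across the two sets (within one pair per class).
#'
#' @param pairs A `sib_pairs` data frame.
#' @param discovery_fraction Fraction assigned to the discovery set, in
#'   (0, 1).  `750/1253` mirrors a 1,253-pair cohort split into 750 + 503.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with `discovery` and `validation` data frames.
#' @export
split_discovery_validation <- function(pairs, discovery_fraction, seed = 1) {
  if (discovery_fraction <= 0 || discovery_fraction >= 1)
    stop("discovery_fraction must be in (0, 1)", call. = FALSE)
  # stratify on the sib phenotype; with single-class tables (e.g. all
  # discordant pairs oriented proband-affected) this is a plain random split
  y <- pairs$pheno_sib
  set.seed(seed)
  take <- logical(nrow(pairs))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_disc <- round(length(idx) * discovery_fraction)
    take[sample(idx, n_disc)] <- TRUE
  }
  list(discovery = pairs[take, , drop = FALSE],
       validation = pairs[!take, , drop = FALSE])
}

# -- ROC ---------------------------------------------------------------------

#' ROC curve, AUC and Hanley-McNeil standard error
#'
#' Sweeps thresholds at midpoints between consecutive unique scores (plus
#' sentinels), giving the full piecewise ROC from (0,0) to (1,1).  The AUC
#' is computed by the Mann-Whitney identity — the probability that a random
#' case outscores a random control, ties counting one half — via ranks, so
#' it is exact and invariant under monotone transforms of the scores.  The
#' standard error is Hanley-McNeil; the 95\% CI is the normal interval
#' truncated to \[0, 1\].
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1 = case).
#' @return Object of class `"roc_result"`: `points` (data frame `fpr`,
#'   `tpr`, `threshold`), `auc`, `se`, `ci95`, `n_cases`, `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  # Mann-Whitney AUC via ranks (ties get average rank = 1/2 weight)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep: classify positive when score > t
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pts <- t(vapply(thr, function(t) {
    pos <- scores > t
    c(fpr = sum(pos & y == 0) / n0, tpr = sum(pos & y == 1) / n1)
  }, c(fpr = 0, tpr = 0)))
  pts <- data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"], threshold = thr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  se <- hanley_mcneil_se(auc, n1, n0)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))
  structure(list(points = pts, auc = auc, se = se, ci95 = ci,
                 n_cases = n1, n_controls = n0),
            class = "roc_result")
}

#' Hanley-McNeil standard error of an AUC
#'
#' @param auc Area under the curve.
#' @param n_cases,n_controls Class counts.
#' @return Standard error.
#' @export
hanley_mcneil_se <- function(auc, n_cases, n_controls) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_cases - 1) * (q1 - auc^2) +
          (n_controls - 1) * (q2 - auc^2)) / (n_cases * n_controls))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (se %.3f, 95%% CI %.3f-%.3f), %d cases / %d controls, %d vertices\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls,
              nrow(x$points)))
  invisible(x)
}

#' Single-indicator DR3/4 baseline model
#'
#' Comparison arm: a one-feature logistic fit of disease status on a
#' binary high-risk HLA-DR3/4 presence indicator, with its ROC, on the
#' same mirrored per-individual observations as the 9-feature model
#' (see [pair_observations()]).  The ROC of a binary test has exactly
#' three vertices.
#'
#' @param pairs A `sib_pairs` data frame with `dr34_proband` and
#'   `dr34_sib` 0/1 columns.
#' @param indicator,labels Alternatively, an explicit indicator/label
#'   pair (both vectors); `pairs` is ignored when given.
#' @return List with `model` (a `"sib_logit"`) and `roc` (a `"roc_result"`).
#' @export
dr34_baseline <- function(pairs = NULL, indicator = NULL, labels = NULL) {
  if (is.null(indicator)) {
    obs <- pair_observations(pairs)
    if (is.null(obs$dr34))
      stop("pair table lacks dr34_proband/dr34_sib indicator columns",
           call. = FALSE)
    indicator <- obs$dr34
    labels <- obs$labels
  }
  X <- matrix(as.numeric(indicator), ncol = 1, dimnames = list(NULL, "dr34"))
  # a perfectly predictive indicator separates completely; the ROC of a
  # binary test is still well-defined, so fall back to a tiny ridge
  model <- tryCatch(fit_logistic(X, labels), error = function(e) {
    message("indicator separates the classes; refitting with a small ridge")
    fit_logistic(X, labels, ridge = 1e-6)
  })
  scores <- predict_risk(model, X)$logit
  list(model = model, roc = roc_curve(scores, labels))
}

# -- screening metrics -------------------------------------------------------

#' Prevalence-dependent screening metrics
#'
#' Converts an operating point (sensitivity, specificity) and a population
#' prevalence into predictive values by Bayes' rule:
#' \deqn{PPV = \frac{se\,K}{se\,K + (1-sp)(1-K)}, \qquad
#'       NPV = \frac{sp\,(1-K)}{(1-se)\,K + sp\,(1-K)}.}
#' Degenerate zero denominators give PPV = 0 / NPV = 1 with a flag.
#'
#' @param sensitivity,specificity Operating point, in \[0, 1\].
#' @param prevalence_k Prevalence of disease in the screened population.
#' @param threshold_logit Optional score threshold the point came from
#'   (carried through for reporting).
#' @return Object of class `"screening_metrics"`: the inputs plus `ppv`,
#'   `npv`, `degenerate`.
#' @export
screening_metrics <- function(sensitivity, specificity, prevalence_k,
                              threshold_logit = NA_real_) {
  se <- sensitivity; sp <- specificity; K <- prevalence_k
  if (any(c(se, sp) < 0) || any(c(se, sp) > 1))
    stop("sensitivity and specificity must be in [0, 1]", call. = FALSE)
  if (K <= 0 || K >= 1) stop("prevalence must be in (0, 1)", call. = FALSE)
  degenerate <- FALSE
  den_p <- se * K + (1 - sp) * (1 - K)
  den_n <- (1 - se) * K + sp * (1 - K)
  ppv <- if (den_p > 0) se * K / den_p else { degenerate <- TRUE; 0 }
  npv <- if (den_n > 0) sp * (1 - K) / den_n else { degenerate <- TRUE; 1 }
  structure(list(threshold_logit = threshold_logit, sensitivity = se,
                 specificity = sp, prevalence_k = K, ppv = ppv, npv = npv,
                 degenerate = degenerate),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("At K = %g: sens %.3f, spec %.3f -> PPV %.2f%%, NPV %.2f%%\n",
              x$prevalence_k, x$sensitivity, x$specificity,
              100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' Choose an operating point on a ROC curve
#'
#' For rare-disease screening the useful thresholds sit in the lower-left
#' part of the curve: small sensitivity, high specificity.  The default
#' rule picks the vertex maximizing specificity subject to sensitivity at
#' least `min_sensitivity`.
#'
#' @param roc A `"roc_result"`.
#' @param min_sensitivity Sensitivity floor (default 0.3).
#' @return One row of `roc$points` (fpr, tpr, threshold).
#' @export
operating_point <- function(roc, min_sensitivity = 0.3) {
  pts <- roc$points
  ok <- pts$tpr >= min_sensitivity
  if (!any(ok)) stop("no ROC vertex reaches the requested sensitivity",
                     call. = FALSE)
  cand <- pts[ok, ]
  cand[which.max(1 - cand$fpr), ]
}
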