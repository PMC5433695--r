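# Independent oracles used to cross-check the package's own routines.

# least squares through the normal equations, no QR
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# AUC by brute-force enumeration of all case-control score pairs,
# ties counting one half
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# quick sib_pairs constructor
make_pairs <- function(p1, p2, pi_hat, region = NULL, sq_diff = NULL) {
  d <- data.frame(pair_id = sprintf("p%03d", seq_along(p1)),
                  pheno_proband = p1, pheno_sib = p2, pi_hat = pi_hat)
  if (!is.null(region)) d$region <- region
  if (!is.null(sq_diff)) d$sq_diff <- sq_diff
  class(d) <- c("sib_pairs", "data.frame")
  d
}

# random strata with no slope: pi_hat independent of concordance class
null_strata <- function(n = 120, seed = 99) {
  set.seed(seed)
  mk <- function(p1, p2) make_pairs(rep(p1, n), rep(p2, n),
                                    rnorm(n, 0.5, 0.05))
  list(AA = mk(1, 1), AU = mk(1, 0), UU = mk(0, 0))
}

# response as the package defines it, but computed independently
he_response_oracle <- function(d) {
  if (!is.null(d$sq_diff)) d$sq_diff else (d$pheno_proband - d$pheno_sib)^2
}

observed_h2_quiet <- function(beta, var_p)
  suppressWarnings(observed_h2(beta, var_p))
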