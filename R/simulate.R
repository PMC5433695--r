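# Liability-threshold simulator for sib-pair cohorts.
#
# Phenotypes arise from a latent standard-normal liability; a pair's
# liabilities are bivariate normal with correlation pi_hat * h2 (additive
# sharing only), and disease occurs above the threshold T = qnorm(1 - K).
# Genome-wide IBD sharing is drawn directly as a truncated normal around
# the full-sib expectation; the analyses only ever consume the genome-wide
# proportion, so no chromosome-level recombination process is modelled.

#' Derive a reproducible sub-stream seed
#'
#' One top-level seed fans out to named sub-streams (`"simulate"`,
#' `"split"`, `"bootstrap"`, ...) so a change in one stage's RNG
#' consumption cannot perturb another stage.
#'
#' @param seed Integer master seed.
#' @param stream Stream name.
#' @return An integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Simulation configuration for sib-pair cohorts
#'
#' Defaults describe a type-1-diabetes-like cohort: liability-scale
#' heritability 0.8 (mid-range of twin estimates for the disease),
#' population prevalence 0.005, IBD sharing centred on 0.5 with the
#' theoretical full-sib standard deviation 0.04 (`ibd_sd = 0.056`
#' reproduces the noisier marker-estimated spread seen in real data), and
#' three strong HLA-tag-like biallelic SNPs.
#'
#' @param n_pairs Number of sib pairs.
#' @param h2_true Liability-scale narrow-sense heritability in \[0, 1\].
#' @param prevalence_k Population prevalence K in (0, 1).
#' @param ibd_mean,ibd_sd Mean and sd of the genome-wide IBD proportion.
#' @param ibd_range Truncation interval for \eqn{\hat\pi}.
#' @param snp_freq Risk-allele frequencies of the three SNPs.
#' @param snp_beta Per-allele log-odds of the three SNPs.
#' @param polygenic_sd SD of the shared polygenic term on the logit scale
#'   (genotype simulation only); sib-pair correlation of the term is
#'   \eqn{\hat\pi}.
#' @param dr34_penetrance P(DR3/4 flag | high-risk two-locus genotype);
#'   background rate is `dr34_background`.
#' @param dr34_background P(DR3/4 flag | other genotypes).
#' @param ascertain_proband Require an affected proband per pair.
#' @param region_count,region_sd Number of regions and sd of the shared
#'   per-region liability intercept (0 regions disables the term).
#' @param seed Master seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_pairs = 1000, h2_true = 0.8, prevalence_k = 0.005,
                       ibd_mean = 0.5, ibd_sd = 0.04, ibd_range = c(0, 1),
                       snp_freq = c(0.25, 0.35, 0.30),
                       snp_beta = log(c(3.0, 2.5, 2.0)),
                       polygenic_sd = 1.3,
                       dr34_penetrance = 0.8, dr34_background = 0.1,
                       ascertain_proband = FALSE,
                       region_count = 0, region_sd = 0.05, seed = 1) {
  cfg <- list(n_pairs = as.integer(n_pairs), h2_true = h2_true,
              prevalence_k = prevalence_k, ibd_mean = ibd_mean,
              ibd_sd = ibd_sd, ibd_range = ibd_range,
              snp_freq = snp_freq, snp_beta = snp_beta,
              polygenic_sd = polygenic_sd,
              dr34_penetrance = dr34_penetrance,
              dr34_background = dr34_background,
              ascertain_proband = isTRUE(ascertain_proband),
              region_count = as.integer(region_count),
              region_sd = region_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop(sprintf("invalid config field '%s': %s", field, msg),
                  call. = FALSE)
  chk(cfg$n_pairs >= 1, "n_pairs", "need at least one pair")
  chk(cfg$h2_true >= 0 && cfg$h2_true <= 1, "h2_true", "must be in [0, 1]")
  chk(cfg$prevalence_k > 0 && cfg$prevalence_k < 1, "prevalence_k",
      "must be in (0, 1)")
  chk(cfg$ibd_mean > 0 && cfg$ibd_mean < 1, "ibd_mean", "must be in (0, 1)")
  chk(cfg$ibd_sd > 0, "ibd_sd", "must be positive")
  chk(length(cfg$snp_freq) == 3 && all(cfg$snp_freq > 0 & cfg$snp_freq < 1),
      "snp_freq", "three frequencies in (0, 1)")
  chk(length(cfg$snp_beta) == 3, "snp_beta", "three per-allele log-odds")
  chk(all(c(cfg$dr34_penetrance, cfg$dr34_background) >= 0 &
            c(cfg$dr34_penetrance, cfg$dr34_background) <= 1),
      "dr34_penetrance", "probabilities in [0, 1]")
  chk(cfg$region_count >= 0, "region_count", "must be >= 0")
  chk(cfg$region_sd >= 0, "region_sd", "must be >= 0")
  invisible(cfg)
}

#' Draw genome-wide IBD proportions
#'
#' Truncated-normal draws via inverse-CDF, so every draw costs one
#' uniform: reproducible and rejection-free.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal.
#' @param lower,upper Truncation bounds (defaults 0 and 1).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used when a caller manages seeding).
#' @return Numeric vector of \eqn{\hat\pi} values.
#' @export
simulate_ibd <- function(n, mean = 0.5, sd = 0.04, lower = 0, upper = 1,
                         seed = NULL) {
  if (mean <= 0 || mean >= 1 || sd <= 0)
    stop("need mean in (0, 1) and sd > 0", call. = FALSE)
  if (lower >= upper) stop("lower must be below upper", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# draw one batch of unascertained liability pairs; RNG state is external
liability_batch <- function(n, cfg) {
  pi_hat <- simulate_ibd(n, cfg$ibd_mean, cfg$ibd_sd,
                         cfg$ibd_range[1], cfg$ibd_range[2])
  r <- pmin(pmax(pi_hat * cfg$h2_true, -0.999), 0.999)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  l1 <- z1
  l2 <- r * z1 + sqrt(1 - r^2) * z2
  region <- NULL
  if (cfg$region_count > 0) {
    region <- sample.int(cfg$region_count, n, replace = TRUE)
    shift <- stats::rnorm(cfg$region_count, 0, cfg$region_sd)[region]
    l1 <- l1 + shift
    l2 <- l2 + shift
  }
  thr <- stats::qnorm(1 - cfg$prevalence_k)
  out <- data.frame(pheno_proband = as.integer(l1 > thr),
                    pheno_sib = as.integer(l2 > thr),
                    pi_hat = pi_hat)
  if (!is.null(region)) out$region <- paste0("R", region)
  out
}

#' Simulate sib pairs under the liability-threshold model
#'
#' Each pair's liabilities are bivariate standard normal with correlation
#' \eqn{\hat\pi h^2}; disease is liability above \eqn{\Phi^{-1}(1-K)}.
#' With `ascertain_proband` the first member is required to be affected
#' (rejection sampling), emulating proband-based recruitment.
#'
#' @param config A [sim_config()].
#' @return A `sib_pairs` data frame with `pair_id`, phenotypes, `pi_hat`
#'   and (when regions are simulated) `region`.
#' @export
simulate_liability_pairs <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(derive_seed(cfg$seed, "liability"))
  n <- cfg$n_pairs
  if (!cfg$ascertain_proband) {
    out <- liability_batch(n, cfg)
  } else {
    got <- list(); n_got <- 0L; attempts <- 0
    batch <- max(1000L, ceiling(n / max(cfg$prevalence_k, 1e-4)))
    while (n_got < n) {
      attempts <- attempts + batch
      if (attempts > 1e7)
        stop("ascertainment rejection exceeded 1e7 attempts; increase prevalence_k",
             call. = FALSE)
      b <- liability_batch(batch, cfg)
      b <- b[b$pheno_proband == 1L, , drop = FALSE]
      if (nrow(b)) { got[[length(got) + 1L]] <- b; n_got <- n_got + nrow(b) }
    }
    out <- do.call(rbind, got)[seq_len(n), , drop = FALSE]
  }
  out <- cbind(pair_id = sprintf("pair%06d", seq_len(n)), out)
  rownames(out) <- NULL
  class(out) <- c("sib_pairs", "data.frame")
  out
}

#' Simulate concordance strata directly
#'
#' Draws unascertained pairs from the liability model and keeps them until
#' each concordance class (AA, AU, UU) reaches its target size.  This
#' conditional sampling reproduces the class-specific IBD distributions
#' \eqn{p(\hat\pi \mid \text{class})} that the stratified bootstrap
#' consumes, without simulating the (huge) base population.
#'
#' @param config A [sim_config()]; `n_pairs` is ignored.
#' @param n_per_class Target size of each stratum (recycled to length 3,
#'   order AA, AU, UU).
#' @param max_draws Cap on total base draws.
#' @return Named list of `sib_pairs` data frames `AA`, `AU`, `UU`.
#' @export
simulate_strata <- function(config, n_per_class = 400, max_draws = 2e7) {
  cfg <- validate_sim_config(config)
  target <- stats::setNames(rep_len(n_per_class, 3L), c("AA", "AU", "UU"))
  set.seed(derive_seed(cfg$seed, "strata"))
  got <- list(AA = list(), AU = list(), UU = list())
  n_got <- c(AA = 0L, AU = 0L, UU = 0L)
  drawn <- 0
  batch <- 200000L
  while (any(n_got < target)) {
    drawn <- drawn + batch
    if (drawn > max_draws)
      stop(sprintf("stratum filling exceeded %g draws (have AA=%d AU=%d UU=%d)",
                   max_draws, n_got["AA"], n_got["AU"], n_got["UU"]),
           call. = FALSE)
    b <- liability_batch(batch, cfg)
    cls <- c("UU", "AU", "AA")[b$pheno_proband + b$pheno_sib + 1L]
    for (s in c("AA", "AU", "UU")) {
      if (n_got[s] >= target[s]) next
      sub <- b[cls == s, , drop = FALSE]
      if (nrow(sub)) {
        got[[s]][[length(got[[s]]) + 1L]] <- sub
        n_got[s] <- n_got[s] + nrow(sub)
      }
    }
  }
  out <- lapply(stats::setNames(c("AA", "AU", "UU"), c("AA", "AU", "UU")),
                function(s) {
                  d <- do.call(rbind, got[[s]])[seq_len(target[s]), , drop = FALSE]
                  d <- cbind(pair_id = sprintf("%s%06d", s, seq_len(nrow(d))), d)
                  rownames(d) <- NULL
                  class(d) <- c("sib_pairs", "data.frame")
                  d
                })
  out
}

# population risk calibration: choose b0 so that E[plogis(b0 + eta)] = K,
# integrating over HWE genotype frequencies and the polygenic normal
calibrate_intercept <- function(cfg) {
  g_list <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2)
  pr <- function(g, f) stats::dbinom(g, 2, f)
  w <- pr(g_list$g1, cfg$snp_freq[1]) * pr(g_list$g2, cfg$snp_freq[2]) *
    pr(g_list$g3, cfg$snp_freq[3])
  eta_g <- as.matrix(g_list) %*% cfg$snp_beta
  # Gauss-Legendre-style grid over the polygenic term
  a <- seq(-6, 6, length.out = 121) * cfg$polygenic_sd
  wa <- stats::dnorm(a, 0, cfg$polygenic_sd)
  wa <- wa / sum(wa)
  risk <- function(b0) {
    m <- outer(drop(eta_g), a, "+") + b0
    sum((stats::plogis(m) %*% wa) * w)
  }
  stats::uniroot(function(b0) risk(b0) - cfg$prevalence_k,
                 lower = -40, upper = 10, tol = 1e-10)$root
}

#' Simulate sib pairs with Mendelian 3-SNP genotypes
#'
#' For each family, two parents receive haplotypes from the risk-allele
#' frequencies (Hardy-Weinberg); each of two sibs inherits one random
#' allele per parent per SNP.  Disease status follows a logistic model:
#' intercept calibrated so the population risk equals `prevalence_k`, plus
#' the per-allele `snp_beta` effects, plus a shared polygenic term with
#' sib-pair correlation \eqn{\hat\pi}.  A synthetic DR3/4 flag is drawn
#' with probability `dr34_penetrance` for carriers of at least one risk
#' allele at both of SNPs 2 and 3 (the high-risk two-locus configuration)
#' and `dr34_background` otherwise.  With `ascertain_proband`, families
#' without an affected child are rejected and the proband is a random
#' affected child.
#'
#' @param config A [sim_config()].
#' @return A `sib_pairs` data frame with phenotypes, `pi_hat`, dosage
#'   columns `snp1_p..snp3_s`, and `dr34_proband`/`dr34_sib` flags.
#' @export
simulate_genotype_pairs <- function(config) {
  cfg <- validate_sim_config(config)
  b0 <- calibrate_intercept(cfg)
  set.seed(derive_seed(cfg$seed, "genotype"))
  n <- cfg$n_pairs
  draw <- function(m) {
    # parental alleles per SNP: 4 founder alleles, sibs draw 1 per parent
    g_s1 <- matrix(0L, m, 3); g_s2 <- matrix(0L, m, 3)
    for (j in 1:3) {
      pa <- matrix(stats::rbinom(2 * m, 1, cfg$snp_freq[j]), m, 2)  # father
      ma <- matrix(stats::rbinom(2 * m, 1, cfg$snp_freq[j]), m, 2)  # mother
      pick <- function(al) al[cbind(seq_len(m), sample(1:2, m, TRUE))]
      g_s1[, j] <- pick(pa) + pick(ma)
      g_s2[, j] <- pick(pa) + pick(ma)
    }
    pi_hat <- simulate_ibd(m, cfg$ibd_mean, cfg$ibd_sd,
                           cfg$ibd_range[1], cfg$ibd_range[2])
    r <- pmin(pmax(pi_hat, 0), 0.999)
    a1 <- stats::rnorm(m, 0, cfg$polygenic_sd)
    a2 <- r * a1 + sqrt(1 - r^2) * stats::rnorm(m, 0, cfg$polygenic_sd)
    p1 <- stats::rbinom(m, 1, stats::plogis(b0 + drop(g_s1 %*% cfg$snp_beta) + a1))
    p2 <- stats::rbinom(m, 1, stats::plogis(b0 + drop(g_s2 %*% cfg$snp_beta) + a2))
    dr34 <- function(g) {
      hr <- g[, 2] >= 1 & g[, 3] >= 1
      stats::rbinom(m, 1, ifelse(hr, cfg$dr34_penetrance, cfg$dr34_background))
    }
    list(g1 = g_s1, g2 = g_s2, p1 = p1, p2 = p2, pi_hat = pi_hat,
         d1 = dr34(g_s1), d2 = dr34(g_s2))
  }
  assemble <- function(b, proband_is_1) {
    i1 <- ifelse(proband_is_1, 1, 2)
    gp <- b$g1; gs <- b$g2
    swap <- !proband_is_1
    gp[swap, ] <- b$g2[swap, ]; gs[swap, ] <- b$g1[swap, ]
    data.frame(pheno_proband = ifelse(proband_is_1, b$p1, b$p2),
               pheno_sib = ifelse(proband_is_1, b$p2, b$p1),
               pi_hat = b$pi_hat,
               snp1_p = gp[, 1], snp2_p = gp[, 2], snp3_p = gp[, 3],
               snp1_s = gs[, 1], snp2_s = gs[, 2], snp3_s = gs[, 3],
               dr34_proband = ifelse(proband_is_1, b$d1, b$d2),
               dr34_sib = ifelse(proband_is_1, b$d2, b$d1))
  }
  if (!cfg$ascertain_proband) {
    b <- draw(n)
    out <- assemble(b, rep(TRUE, n))
  } else {
    got <- list(); n_got <- 0L; attempts <- 0
    # P(family has an affected child) ~ 2K x enrichment; batch generously
    batch <- max(2000L, ceiling(n / max(2 * cfg$prevalence_k, 1e-4)))
    while (n_got < n) {
      attempts <- attempts + batch
      if (attempts > 1e7)
        stop("ascertainment rejection exceeded 1e7 attempts; increase prevalence_k",
             call. = FALSE)
      b <- draw(batch)
      any_aff <- b$p1 == 1 | b$p2 == 1
      both <- b$p1 == 1 & b$p2 == 1
      proband_is_1 <- b$p1 == 1
      # when both affected, pick the proband at random
      proband_is_1[both] <- stats::runif(sum(both)) < 0.5
      d <- assemble(b, proband_is_1)[any_aff, , drop = FALSE]
      if (nrow(d)) { got[[length(got) + 1L]] <- d; n_got <- n_got + nrow(d) }
    }
    out <- do.call(rbind, got)[seq_len(n), , drop = FALSE]
  }
  out <- cbind(pair_id = sprintf("fam%06d:1:fam%06d:2",
                                 seq_len(n), seq_len(n)), out)
  rownames(out) <- NULL
  class(out) <- c("sib_pairs", "data.frame")
  out
}

#' Write a simulated fixture set to disk
#'
#' Emits three files that round-trip through the package readers: a
#' PLINK-dialect `.genome` IBD table (Z probabilities reconstructed from
#' \eqn{\hat\pi} as \eqn{z_2 = \hat\pi^2, z_1 = 2\hat\pi(1-\hat\pi)}), a
#' pair-table TSV and a JSON echo of the configuration, plus a manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @param with_genotypes Simulate genotypes (default) or liability-only
#'   pairs.
#' @return Data frame manifest: `file`, `rows`; written alongside as
#'   `manifest.tsv`.
#' @export
write_fixture_set <- function(config, out_dir, with_genotypes = TRUE) {
  cfg <- validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- if (with_genotypes) simulate_genotype_pairs(cfg)
           else simulate_liability_pairs(cfg)
  n <- nrow(pairs)
  ibd <- data.frame(FID1 = sprintf("fam%06d", seq_len(n)), IID1 = 1L,
                    FID2 = sprintf("fam%06d", seq_len(n)), IID2 = 2L,
                    Z0 = (1 - pairs$pi_hat)^2,
                    Z1 = 2 * pairs$pi_hat * (1 - pairs$pi_hat),
                    Z2 = pairs$pi_hat^2,
                    PI_HAT = pairs$pi_hat)
  f_genome <- file.path(out_dir, "pairs.genome")
  f_pairs <- file.path(out_dir, "pairs.tsv")
  f_cfg <- file.path(out_dir, "config.json")
  write_plink_genome(ibd, f_genome)
  write_pair_table(pairs, f_pairs)
  jsonlite::write_json(unclass(cfg), f_cfg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- data.frame(file = c(basename(f_genome), basename(f_pairs),
                                  basename(f_cfg)),
                         rows = c(n, n, NA))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
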