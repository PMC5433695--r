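# End-to-end pipelines behind the command-line entry points.  Each run
# takes one master seed, fans it out to named sub-streams, and echoes the
# configuration and seed into every artifact it writes, so any report can
# be regenerated bit-identically.

#' Heritability pipeline
#'
#' Reads (or accepts) a sib-pair table with IBD sharing, splits it into
#' concordance strata, runs the stratified bootstrap once, and reports the
#' liability-scale heritability at each requested prevalence.
#'
#' @param pairs A `sib_pairs` data frame (or path to a pair table with a
#'   `pi_hat` column).
#' @param prevalences Prevalence settings K (non-empty).
#' @param n_per_stratum,replicates Bootstrap design.
#' @param seed Master seed.
#' @param use_regions Fit the region random-intercept model inside each
#'   replicate when region labels are present.
#' @param out_dir Optional directory: writes `heritability.tsv` and
#'   `heritability.json` (report + config echo).
#' @return The report data frame (see [heritability_report()]),
#'   with attributes `seed` and `strata_n`.
#' @export
run_heritability <- function(pairs, prevalences, n_per_stratum = 300,
                             replicates = 10000, seed = 1,
                             use_regions = FALSE, out_dir = NULL) {
  if (is.character(pairs)) pairs <- read_pair_table(pairs)
  if (is.null(pairs$pi_hat) || anyNA(pairs$pi_hat))
    stop("pairs must carry complete pi_hat values (join an IBD table first)",
         call. = FALSE)
  strata <- split_strata(pairs)
  rep_tab <- heritability_report(strata, prevalences,
                                 n_per_stratum = n_per_stratum,
                                 replicates = replicates,
                                 seed = derive_seed(seed, "bootstrap"),
                                 use_regions = use_regions)
  attr(rep_tab, "seed") <- as.integer(seed)
  attr(rep_tab, "strata_n") <- vapply(strata, nrow, integer(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rep_tab, file.path(out_dir, "heritability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = as.integer(seed),
           n_per_stratum = n_per_stratum, replicates = replicates,
           strata_n = as.list(attr(rep_tab, "strata_n")),
           report = rep_tab),
      file.path(out_dir, "heritability.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep_tab
}

#' Risk-model pipeline
#'
#' Drops incomplete genotypes, keeps discordant (affected/unaffected)
#' pairs, splits the pairs into discovery and validation sets, expands
#' each set into mirrored per-individual observations
#' ([pair_observations()]; both observations of a pair stay in the same
#' set, so there is no leakage), fits the 9-feature logistic model on the
#' discovery observations, evaluates ROC/AUC on both sets, fits the DR3/4
#' single-indicator baseline when the flag is available, and computes
#' PPV/NPV at the requested prevalences from the default operating point
#' (maximum specificity with sensitivity >= `min_sensitivity`).
#'
#' @param pairs A `sib_pairs` data frame (or path) with genotype columns.
#' @param discovery_fraction Fraction of pairs in the discovery set.
#' @param prevalences Prevalences for the screening metrics.
#' @param min_sensitivity Sensitivity floor for the operating point.
#' @param seed Master seed.
#' @param out_dir Optional directory: writes `risk_report.json` and
#'   `roc_points.tsv`.
#' @return List of class `"risk_report"`: `model`, `roc_discovery`,
#'   `roc_validation`, `baseline` (or NULL), `operating_point`,
#'   `screening` (list of [screening_metrics()]), `seed`, `n`.
#' @export
run_risk <- function(pairs, discovery_fraction = 750 / 1253,
                     prevalences = c(0.01, 0.03), min_sensitivity = 0.3,
                     seed = 1, out_dir = NULL) {
  if (is.character(pairs)) pairs <- read_pair_table(pairs)
  if (!all(.snp_cols %in% names(pairs)))
    stop(sprintf("pair table lacks genotype column(s): %s",
                 paste(setdiff(.snp_cols, names(pairs)), collapse = ", ")),
         call. = FALSE)
  pairs <- drop_incomplete_genotypes(pairs)
  disc <- pairs$pheno_proband != pairs$pheno_sib
  if (any(!disc))
    message(sprintf("excluded %d concordant pair(s) from the risk analysis",
                    sum(!disc)))
  pairs <- pairs[disc, , drop = FALSE]
  sets <- split_discovery_validation(pairs, discovery_fraction,
                                     seed = derive_seed(seed, "split"))
  obs_d <- suppressMessages(pair_observations(sets$discovery))
  obs_v <- suppressMessages(pair_observations(sets$validation))
  model <- fit_logistic(obs_d$features, obs_d$labels)
  roc_d <- roc_curve(predict_risk(model, obs_d$features)$logit, obs_d$labels)
  roc_v <- roc_curve(predict_risk(model, obs_v$features)$logit, obs_v$labels)
  baseline <- if (!is.null(obs_d$dr34))
    dr34_baseline(indicator = obs_d$dr34, labels = obs_d$labels)
  op <- operating_point(roc_d, min_sensitivity)
  screening <- lapply(prevalences, function(K)
    screening_metrics(sensitivity = op$tpr, specificity = 1 - op$fpr,
                      prevalence_k = K, threshold_logit = op$threshold))
  out <- structure(list(model = model, roc_discovery = roc_d,
                        roc_validation = roc_v, baseline = baseline,
                        operating_point = op, screening = screening,
                        seed = as.integer(seed), n = nrow(pairs)),
                   class = "risk_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(roc_d$points, file.path(out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(risk_report_json(out),
                         file.path(out_dir, "risk_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

risk_report_json <- function(x) {
  roc_bits <- function(r) list(auc = r$auc, se = r$se, ci95 = r$ci95,
                               n_cases = r$n_cases, n_controls = r$n_controls)
  list(seed = x$seed, n_pairs = x$n,
       coefficients = as.list(x$model$coefficients),
       coefficient_se = as.list(x$model$se),
       converged = x$model$converged,
       auc_discovery = roc_bits(x$roc_discovery),
       auc_validation = roc_bits(x$roc_validation),
       auc_baseline = if (!is.null(x$baseline)) roc_bits(x$baseline$roc),
       operating_point = as.list(x$operating_point),
       screening = lapply(x$screening, unclass))
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("Sib-pair risk model on %d pairs (seed %d)\n", x$n, x$seed))
  cat(sprintf("  discovery  AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$roc_discovery$auc, x$roc_discovery$ci95[1],
              x$roc_discovery$ci95[2]))
  cat(sprintf("  validation AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$roc_validation$auc, x$roc_validation$ci95[1],
              x$roc_validation$ci95[2]))
  if (!is.null(x$baseline))
    cat(sprintf("  DR3/4 baseline AUC %.3f\n", x$baseline$roc$auc))
  cat(sprintf("  operating point: sens %.3f, spec %.3f (logit > %.3f)\n",
              x$operating_point$tpr, 1 - x$operating_point$fpr,
              x$operating_point$threshold))
  for (s in x$screening)
    cat(sprintf("    K = %-5g PPV %5.2f%%  NPV %5.2f%%\n",
                s$prevalence_k, 100 * s$ppv, 100 * s$npv))
  invisible(x)
}

#' Simulation command
#'
#' Thin wrapper over [write_fixture_set()] used by the command-line
#' entry point: builds a [sim_config()] from a named list (e.g. parsed
#' from YAML/JSON) and writes a fixture set.
#'
#' @param config Named list of [sim_config()] arguments, or a path to a
#'   JSON/YAML file of them.
#' @param out_dir Output directory.
#' @param seed Optional override of the config seed.
#' @return The manifest data frame.
#' @export
cmd_simulate <- function(config = list(), out_dir, seed = NULL) {
  cfg_args <- read_config(config)
  if (!is.null(seed)) cfg_args$seed <- as.integer(seed)
  cfg <- do.call(sim_config, cfg_args)
  write_fixture_set(cfg, out_dir)
}

#' Heritability command
#'
#' @param ibd_path PLINK `.genome`-style file.
#' @param pairs_path Pair-table TSV.
#' @param prevalences Prevalence settings K.
#' @param out_dir Output directory.
#' @param ... Passed to [run_heritability()].
#' @return The report data frame.
#' @export
cmd_heritability <- function(ibd_path, pairs_path, prevalences,
                             out_dir = NULL, ...) {
  pairs <- read_pair_table(pairs_path)
  if (is.null(pairs$pi_hat) || anyNA(pairs$pi_hat)) {
    if (is.null(ibd_path))
      stop("pair table has no pi_hat column and no IBD file was given",
           call. = FALSE)
    ibd <- read_plink_genome(ibd_path)
    pairs <- join_pairs_ibd(pairs, ibd, by = "order")
  }
  run_heritability(pairs, prevalences, out_dir = out_dir, ...)
}

#' Risk command
#'
#' @param pairs_path Pair-table TSV with genotype columns.
#' @param out_dir Output directory.
#' @param ... Passed to [run_risk()].
#' @return A `"risk_report"`.
#' @export
cmd_risk <- function(pairs_path, out_dir = NULL, ...) {
  run_risk(read_pair_table(pairs_path), out_dir = out_dir, ...)
}

read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config))
    stop(sprintf("config file not found: '%s'", config), call. = FALSE)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}
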