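# -- PLINK .genome dialect ---------------------------------------------------
# Accepted headers: the full PLINK set (FID1 IID1 FID2 IID2 RT EZ Z0 Z1 Z2
# PI_HAT ...) or any trimmed variant that still carries PI_HAT or Z1/Z2.
# Columns are matched by name, never by position.

.genome_id_cols <- c("FID1", "IID1", "FID2", "IID2")

#' Compute the genome-wide IBD proportion from Z probabilities
#'
#' The genome-wide proportion of alleles shared identical by descent is
#' \eqn{\hat\pi = Z_1/2 + Z_2}, where \eqn{Z_k} is the probability of
#' sharing \eqn{k} alleles IBD.  Full siblings have expectation 0.5.
#'
#' @param z0,z1,z2 Numeric vectors of IBD state probabilities; each element
#'   must lie in \[0, 1\] and each triple must sum to 1 within `tol`.
#' @param tol Allowed deviation of `z0 + z1 + z2` from 1 (default `1e-3`).
#' @return Numeric vector of \eqn{\hat\pi} values in \[0, 1\].
#' @examples
#' pi_hat_from_z(0.25, 0.5, 0.25)  # expected full-sib sharing, 0.5
#' @export
pi_hat_from_z <- function(z0, z1, z2, tol = 1e-3) {
  z <- cbind(z0, z1, z2)
  if (any(!is.finite(z)) || any(z < 0) || any(z > 1))
    stop("Z probabilities must be finite and in [0, 1]", call. = FALSE)
  bad <- abs(rowSums(z) - 1) > tol
  if (any(bad))
    stop(sprintf("Z0 + Z1 + Z2 deviates from 1 by more than %g in %d row(s) (first: row %d, sum %.6f)",
                 tol, sum(bad), which(bad)[1], rowSums(z)[which(bad)[1]]),
         call. = FALSE)
  unname(z[, 2] / 2 + z[, 3])
}

#' Read a PLINK \code{.genome}-style IBD table
#'
#' Parses a whitespace-delimited table with a header row, as written by
#' \code{plink --genome}.  Trimmed dialects are accepted: the header must
#' contain \code{PI_HAT}, or \code{Z1} and \code{Z2} from which
#' \eqn{\hat\pi} is reconstructed.  When both are present and disagree by
#' more than `tol`, \code{PI_HAT} wins (it is the quantity the downstream
#' regression uses) and a warning reports the disagreement.
#'
#' @param path Path to the file.
#' @param tol Consistency tolerance between `PI_HAT` and `Z1/2 + Z2`.
#' @return A data frame of class `"ibd_table"` with columns `FID1`, `IID1`,
#'   `FID2`, `IID2` (when present in the file), `Z0`, `Z1`, `Z2` (when
#'   present) and `PI_HAT`; one row per input data row, order preserved.
#' @seealso [write_plink_genome()], [pi_hat_from_z()]
#' @export
read_plink_genome <- function(path, tol = 1e-3) {
  if (!file.exists(path))
    stop(sprintf("IBD file not found: '%s'", path), call. = FALSE)
  header <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  if (length(header) == 0L)
    stop(sprintf("'%s' is empty: expected a header row", path), call. = FALSE)
  has_z  <- all(c("Z1", "Z2") %in% header)
  has_ph <- "PI_HAT" %in% header
  if (!has_z && !has_ph)
    stop(sprintf("header of '%s' lacks both PI_HAT and Z1/Z2 columns (found: %s)",
                 path, paste(header, collapse = " ")), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(raw) == 0L) {
    out <- raw[, intersect(c(.genome_id_cols, "Z0", "Z1", "Z2", "PI_HAT"),
                           names(raw)), drop = FALSE]
    if (!"PI_HAT" %in% names(out)) out$PI_HAT <- numeric(0)
    class(out) <- c("ibd_table", "data.frame")
    return(out)
  }
  num_cols <- intersect(c("Z0", "Z1", "Z2", "PI_HAT"), names(raw))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column %s at data row %d of '%s'",
                   raw[[cc]][bad[1]], cc, bad[1], path), call. = FALSE)
    raw[[cc]] <- v
  }
  out <- raw[, intersect(c(.genome_id_cols, "Z0", "Z1", "Z2", "PI_HAT"),
                         names(raw)), drop = FALSE]
  if (has_z) {
    if (!"Z0" %in% names(out)) out$Z0 <- 1 - out$Z1 - out$Z2
    pihat_z <- out$Z1 / 2 + out$Z2
    if (has_ph) {
      off <- abs(out$PI_HAT - pihat_z) > tol
      if (any(off, na.rm = TRUE))
        warning(sprintf("%d row(s) where PI_HAT and Z1/2 + Z2 disagree by more than %g; keeping PI_HAT",
                        sum(off, na.rm = TRUE), tol), call. = FALSE)
    } else {
      out$PI_HAT <- pihat_z
    }
  }
  if (any(out$PI_HAT < 0 | out$PI_HAT > 1, na.rm = TRUE))
    stop("PI_HAT outside [0, 1]", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ibd_table", "data.frame")
  out
}

#' Write an IBD table in PLINK \code{.genome} dialect
#'
#' Numeric fields are written with six decimals, so a write/read round trip
#' reproduces them to that precision.
#'
#' @param x An `ibd_table` (or data frame with the same columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plink_genome <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- as.data.frame(x)
  for (cc in intersect(c("Z0", "Z1", "Z2", "PI_HAT"), names(out)))
    out[[cc]] <- sprintf("%.6f", out[[cc]])
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# -- pair table --------------------------------------------------------------

.snp_cols <- c("snp1_p", "snp2_p", "snp3_p", "snp1_s", "snp2_s", "snp3_s")

#' Read a sib-pair phenotype table
#'
#' The pair table is a tab- or whitespace-delimited file with a header row
#' and columns `pair_id`, `pheno_proband`, `pheno_sib`, plus optional
#' `region`, optional `pi_hat`, optional `dr34_sib`, and optional genotype
#' dosage columns `snp1_p snp2_p snp3_p snp1_s snp2_s snp3_s` coded 0/1/2
#' (NA allowed).  Phenotypes must be 0 (unaffected) or 1 (affected).
#'
#' @param path Path to the file.
#' @return A data frame of class `"sib_pairs"`, one row per proband-sib pair.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("pair table not found: '%s'", path), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."))
  need <- c("pair_id", "pheno_proband", "pheno_sib")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(sprintf("pair table '%s' lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  for (cc in c("pheno_proband", "pheno_sib")) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("phenotype outside {0, 1} in column %s at data row %d of '%s'",
                   cc, bad[1], path), call. = FALSE)
    raw[[cc]] <- as.integer(v)
  }
  for (cc in intersect(c(.snp_cols, "pi_hat", "dr34_sib"), names(raw))) {
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
    if (cc %in% .snp_cols && any(!raw[[cc]] %in% c(0, 1, 2) & !is.na(raw[[cc]])))
      stop(sprintf("genotype dosage outside {0, 1, 2} in column %s of '%s'",
                   cc, path), call. = FALSE)
  }
  rownames(raw) <- NULL
  class(raw) <- c("sib_pairs", "data.frame")
  raw
}

#' Write a sib-pair table
#'
#' @param x A `sib_pairs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- as.data.frame(x)
  if ("pi_hat" %in% names(out)) out$pi_hat <- sprintf("%.6f", out$pi_hat)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Attach IBD sharing to sib pairs
#'
#' Joins an IBD table onto a pair table, either positionally (`by =
#' "order"`: row i of `ibd` belongs to pair i) or by identifier (`by =
#' "id"`: the IBD key `FID1:IID1:FID2:IID2` must match the pair table's
#' `pair_id`).  Unmatched pairs are kept with `pi_hat = NA` and reported
#' via a warning.
#'
#' @param pairs A `sib_pairs` data frame.
#' @param ibd An `ibd_table`.
#' @param by `"order"` or `"id"`.
#' @return `pairs` with a populated `pi_hat` column.
#' @export
join_pairs_ibd <- function(pairs, ibd, by = c("order", "id")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(pairs), is.data.frame(ibd))
  if (by == "order") {
    if (nrow(pairs) != nrow(ibd))
      stop(sprintf("positional join needs equal row counts (%d pairs, %d IBD records)",
                   nrow(pairs), nrow(ibd)), call. = FALSE)
    pairs$pi_hat <- ibd$PI_HAT
  } else {
    if (!all(.genome_id_cols %in% names(ibd)))
      stop("id join needs FID1/IID1/FID2/IID2 columns in the IBD table",
           call. = FALSE)
    key <- paste(ibd$FID1, ibd$IID1, ibd$FID2, ibd$IID2, sep = ":")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      stop(sprintf("duplicate IBD key(s): %s",
                   paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
    idx <- match(as.character(pairs$pair_id), key)
    if (anyNA(idx))
      warning(sprintf("%d pair(s) had no matching IBD record (first: %s)",
                      sum(is.na(idx)),
                      pairs$pair_id[which(is.na(idx))[1]]), call. = FALSE)
    pairs$pi_hat <- ibd$PI_HAT[idx]
  }
  class(pairs) <- unique(c("sib_pairs", class(pairs)))
  pairs
}

#' Classify sib pairs by phenotype concordance
#'
#' @param pairs A `sib_pairs` data frame.
#' @return Factor with levels `AA` (both affected), `AU` (discordant),
#'   `UU` (both unaffected).
#' @export
pair_class <- function(pairs) {
  s <- pairs$pheno_proband + pairs$pheno_sib
  factor(c("UU", "AU", "AA")[s + 1L], levels = c("AA", "AU", "UU"))
}
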