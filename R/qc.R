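#' Minor allele frequency
#'
#' \code{min(p, 1 - p)} with \code{p} the sample frequency of the counted
#' allele over the non-missing dosages in \code{subset}.
#'
#' @param dosages dosage vector (0/1/2/NA) or \code{geno_matrix} column.
#' @param subset optional index/logical/ID subset of individuals over which
#'   the frequency is computed (e.g. founders only).
#' @return frequency in [0, 1/2].
#' @export
minor_allele_frequency <- function(dosages, subset = NULL) {
  if (!is.null(subset)) dosages <- dosages[subset]
  ok <- !is.na(dosages)
  if (!any(ok)) stop("MAF undefined: all dosages missing")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

# p-values of the exact conditional HWE test for every compatible
# heterozygote count, given N diploid individuals carrying n_minor copies
# of the minor allele.  Conditional distribution of the heterozygote
# count h (same parity as n_minor):
#   P(h) = N! n_m! n_M! 2^h / [ n_AA! h! n_aa! (2N)! ]
# computed in log space.  Returns list(h, prob, p) with the two-sided
# p-value p[k] = sum of P over h with P(h) <= P(h_k) (1 + 1e-9).
hwe_pvalues_all <- function(N, n_minor) {
  n_minor <- min(n_minor, 2L * N - n_minor)
  h <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  h <- h[(n_minor - h) / 2L + h <= N]
  naa <- (n_minor - h) / 2L
  nAA <- N - h - naa
  lp <- lgamma(N + 1) + lgamma(n_minor + 1) + lgamma(2 * N - n_minor + 1) +
        h * log(2) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) -
        lgamma(2 * N + 1)
  prob <- exp(lp - max(lp))
  prob <- prob / sum(prob)
  p <- vapply(prob, function(pk) sum(prob[prob <= pk * (1 + 1e-9)]), 0)
  list(h = h, prob = prob, p = pmin(p, 1))
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test on genotype counts: given the allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic sites return p = 1.  In this package the test is applied to
#' founder genotype counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return exact two-sided p-value.
#' @examples
#' hwe_exact_test(25, 0, 25)  # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  N <- n_AA + n_Aa + n_aa
  if (N < 1L) stop("HWE test needs at least one genotype")
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0L) return(1)
  all_p <- hwe_pvalues_all(N, n_minor)
  all_p$p[match(n_Aa, all_p$h)]
}

hwe_from_dosages <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) return(NA_real_)
  hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
}

#' Genotype quality control
#'
#' Order of operations: (1) drop SNPs with call rate below
#' \code{snp_call_rate}; (2) drop individuals whose call rate over the
#' surviving SNPs is below \code{ind_call_rate}; (3) flag (default) or drop
#' SNPs failing the MAF rule, computed over the retained individuals or a
#' designated subset; (4) compute the founder Hardy-Weinberg exact p-value
#' for reporting.  Both the MAF threshold and its comparator are
#' configurable because different analyses use strict ("< 0.03") and
#' non-strict ("<= 0.01") rules.  HWE is report-only by default; an
#' optional hard threshold drops failing SNPs.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param ped a \code{pedigree} (used for the founder HWE test).
#' @param snp_call_rate,ind_call_rate call-rate thresholds; SNPs/individuals
#'   strictly below are excluded (default 0.98).
#' @param maf_min MAF threshold, or \code{NULL} to skip the MAF rule.
#' @param maf_comparator \code{"lt"} excludes MAF < maf_min;
#'   \code{"le"} excludes MAF <= maf_min.
#' @param maf_drop drop MAF-failing SNPs (TRUE) or only flag them (FALSE,
#'   default): flagged SNPs are skipped by the scan but retained for
#'   kinship estimation.
#' @param maf_subset optional individual IDs over which MAF is computed
#'   (default: retained individuals).
#' @param hwe_min optional hard founder-HWE threshold; SNPs with p below it
#'   are dropped (default \code{NULL}: report only).
#' @return list with \code{geno} (filtered \code{geno_matrix}),
#'   \code{individuals} (retained IDs) and \code{report} (a
#'   \code{qc_report}).
#' @export
run_qc <- function(geno, ped = NULL,
                   snp_call_rate = 0.98, ind_call_rate = 0.98,
                   maf_min = NULL, maf_comparator = c("lt", "le"),
                   maf_drop = FALSE, maf_subset = NULL, hwe_min = NULL) {
  maf_comparator <- match.arg(maf_comparator)
  d <- geno$dosage
  n0 <- nrow(d); S0 <- ncol(d)

  # call-rate filtering to a fixed point: dropping individuals changes SNP
  # call rates (and vice versa), so alternate SNP-then-individual passes
  # until stable -- this makes the filter idempotent
  d2 <- d
  excl_snps <- data.frame(snp_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  excl_inds <- data.frame(person_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  snp_cr <- colMeans(!is.na(d2))
  ind_cr <- rowMeans(!is.na(d2))
  repeat {
    snp_cr <- colMeans(!is.na(d2))
    snp_drop <- snp_cr < snp_call_rate
    if (any(snp_drop)) {
      excl_snps <- rbind(excl_snps, data.frame(
        snp_id = colnames(d2)[snp_drop],
        reason = rep("call_rate", sum(snp_drop)), stringsAsFactors = FALSE))
      d2 <- d2[, !snp_drop, drop = FALSE]
    }
    if (ncol(d2) == 0L) stop("QC removed every individual or every SNP")
    ind_cr <- rowMeans(!is.na(d2))
    ind_drop <- ind_cr < ind_call_rate
    if (any(ind_drop)) {
      excl_inds <- rbind(excl_inds, data.frame(
        person_id = rownames(d2)[ind_drop],
        reason = rep("call_rate", sum(ind_drop)), stringsAsFactors = FALSE))
      d2 <- d2[!ind_drop, , drop = FALSE]
    }
    if (nrow(d2) == 0L) stop("QC removed every individual or every SNP")
    if (!any(ind_drop) && !any(snp_drop)) break
  }

  maf_ids <- if (is.null(maf_subset)) rownames(d2) else
    intersect(maf_subset, rownames(d2))
  maf <- apply(d2[maf_ids, , drop = FALSE], 2L, function(v) {
    if (all(is.na(v))) NA_real_ else minor_allele_frequency(v)
  })
  maf_fail <- if (is.null(maf_min)) rep(FALSE, ncol(d2)) else {
    if (maf_comparator == "lt") !is.na(maf) & maf < maf_min
    else !is.na(maf) & maf <= maf_min
  }

  hwe_p <- rep(NA_real_, ncol(d2))
  if (!is.null(ped)) {
    founders <- intersect(ped$person_id[ped$founder], rownames(d2))
    if (length(founders))
      hwe_p <- apply(d2[founders, , drop = FALSE], 2L, hwe_from_dosages)
  }
  hwe_fail <- if (is.null(hwe_min)) rep(FALSE, length(hwe_p)) else
    !is.na(hwe_p) & hwe_p < hwe_min

  drop_now <- (maf_drop & maf_fail) | hwe_fail
  if (any(drop_now)) {
    reason <- ifelse(hwe_fail[drop_now] & !(maf_drop & maf_fail[drop_now]),
                     "hwe", "maf")
    excl_snps <- rbind(excl_snps,
                       data.frame(snp_id = colnames(d2)[drop_now],
                                  reason = reason, stringsAsFactors = FALSE))
  }
  keep_snps <- colnames(d2)[!drop_now]
  out_geno <- geno_subset(geno, individuals = rownames(d2), snps = keep_snps)

  snp_tab <- data.frame(snp_id = colnames(d2), call_rate = snp_cr,
                        maf = maf, hwe_p = hwe_p,
                        maf_fail = maf_fail, stringsAsFactors = FALSE)
  snp_tab <- snp_tab[!drop_now, , drop = FALSE]
  rownames(snp_tab) <- NULL
  report <- structure(list(
    excluded_snps = excl_snps,
    excluded_individuals = excl_inds,
    snp_stats = snp_tab,
    individual_call_rate = data.frame(person_id = rownames(d2),
                                      call_rate = ind_cr,
                                      stringsAsFactors = FALSE),
    thresholds = list(snp_call_rate = snp_call_rate,
                      ind_call_rate = ind_call_rate,
                      maf_min = maf_min, maf_comparator = maf_comparator,
                      maf_drop = maf_drop, hwe_min = hwe_min),
    counts = c(snps_in = S0, snps_out = length(keep_snps),
               individuals_in = n0, individuals_out = nrow(d2))),
    class = "qc_report")
  list(geno = out_geno, individuals = rownames(d2), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  ct <- x$counts
  cat("Quality control summary\n")
  cat(sprintf("  SNPs: %d in, %d retained, %d excluded\n",
              ct["snps_in"], ct["snps_out"], ct["snps_in"] - ct["snps_out"]))
  if (nrow(x$excluded_snps))
    for (r in unique(x$excluded_snps$reason))
      cat(sprintf("    - %s: %d\n", r, sum(x$excluded_snps$reason == r)))
  cat(sprintf("  Individuals: %d in, %d retained, %d excluded\n",
              ct["individuals_in"], ct["individuals_out"],
              ct["individuals_in"] - ct["individuals_out"]))
  nflag <- sum(x$snp_stats$maf_fail)
  if (nflag) cat(sprintf("  SNPs flagged by MAF rule (kept, not tested): %d\n", nflag))
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes \code{<prefix>_snps.tsv}, \code{<prefix>_individuals.tsv} and a
#' human-readable \code{<prefix>_summary.txt}.
#'
#' @param report a \code{qc_report}.
#' @param prefix output path prefix.
#' @export
write_qc_report <- function(report, prefix) {
  utils::write.table(report$snp_stats, paste0(prefix, "_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  excl <- rbind(
    data.frame(id = report$excluded_snps$snp_id,
               what = rep("snp", nrow(report$excluded_snps)),
               reason = report$excluded_snps$reason),
    data.frame(id = report$excluded_individuals$person_id,
               what = rep("individual", nrow(report$excluded_individuals)),
               reason = report$excluded_individuals$reason))
  utils::write.table(excl, paste0(prefix, "_excluded.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, "_summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(prefix)
}
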