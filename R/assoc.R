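# Per-SNP association against a fitted null model.
#
# The SNP enters the mean as T extra design columns (the dosage placed in
# each trait's slot).  The score test evaluates U = Xs' Sinv r and
# V = Xs' P Xs with P = Sinv - Sinv A (A' Sinv A)^-1 A' Sinv, variance
# parameters held at the null MLE, S = U' V^-1 U ~ chi-square(T).  Top
# hits are refined by a full likelihood-ratio refit.

# SNP design block for one pedigree: dosage x (length n_p) placed in each
# trait's slot, observed rows only
snp_block <- function(block, x, T_) {
  Xs <- matrix(0, length(block$obs), T_)
  n_p <- block$n
  for (t in seq_len(T_))
    Xs[(t - 1L) * n_p + seq_len(n_p), t] <- x
  Xs[block$obs, , drop = FALSE]
}

# aligned, mean-imputed dosage for the analyzed individuals
scan_dosage <- function(fit, dosage) {
  if (is.null(names(dosage)))
    stop("dosage vector must be named by person_id")
  x <- dosage[fit$design$ids]
  p <- mean(x, na.rm = TRUE) / 2
  if (is.nan(p)) stop("dosage missing for every analyzed individual")
  x[is.na(x)] <- 2 * p
  x
}

#' Score test for one SNP
#'
#' T-degree-of-freedom score test of the SNP's per-trait mean effects
#' against a fitted null model; no alternative-model iteration is needed.
#' Missing dosages are mean-imputed to twice the sample allele frequency
#' (for testing only, never for kinship).
#'
#' @param fit a \code{\link{pedvc}} null fit.
#' @param dosage numeric vector of minor-allele counts named by
#'   \code{person_id}, covering the analyzed individuals.
#' @return list with \code{stat}, \code{df}, \code{p}; \code{stat} and
#'   \code{p} are \code{NA} with \code{flag = "undefined"} when the score
#'   variance is singular (e.g. constant dosage).
#' @export
score_test <- function(fit, dosage) {
  stopifnot(inherits(fit, "pedvc"))
  T_ <- fit$T
  x <- scan_dosage(fit, dosage)
  k <- length(fit$coefficients)
  U <- numeric(T_); XX <- matrix(0, T_, T_); W <- matrix(0, T_, k)
  for (b in fit$blocks) {
    xs <- x[b$ids]
    Xs <- snp_block(b, xs, T_)
    U <- U + drop(crossprod(Xs, b$Sinv_r))
    SX <- backsolve(b$R, backsolve(b$R, Xs, transpose = TRUE))
    XX <- XX + crossprod(Xs, SX)
    W <- W + crossprod(Xs, b$Sinv_A)
  }
  V <- XX - W %*% fit$Minv %*% t(W)
  # singular V (e.g. dosage constant, hence collinear with the intercept)
  # is judged on the scale of the unprojected information XX
  scale <- max(abs(diag(XX)), 1e-300)
  evV <- tryCatch(eigen(V, symmetric = TRUE, only.values = TRUE)$values,
                  error = function(e) NA_real_)
  ok <- all(is.finite(evV)) && min(evV) > 1e-8 * scale
  if (!ok)
    return(list(stat = NA_real_, df = T_, p = NA_real_, flag = "undefined"))
  S <- drop(crossprod(U, solve(V, U)))
  list(stat = S, df = T_, p = stats::pchisq(S, T_, lower.tail = FALSE),
       flag = "ok")
}

#' Likelihood-ratio test for one SNP
#'
#' Adds T per-trait SNP coefficients to the mean model and fully
#' re-maximizes the likelihood (variance components refit, warm-started
#' at the null estimates).  Reports the statistic 2(L1 - L0), its
#' chi-square(T) p-value and the per-trait SNP effect estimates.
#'
#' @inheritParams score_test
#' @return list with \code{stat}, \code{df}, \code{p}, \code{effects}
#'   (named per-trait coefficients), \code{converged}.
#' @export
lrt <- function(fit, dosage) {
  stopifnot(inherits(fit, "pedvc"))
  T_ <- fit$T
  x <- scan_dosage(fit, dosage)
  design1 <- augment_design(fit$design, x, fit$traits)
  Kb <- restructure_blocks(fit$structures, design1)
  ctl <- default_control(list())
  nll <- function(th) vc_profile(th, design1, Kb, fit$components, "nll")
  opt <- optimize_nll(fit$theta, nll, ctl)
  conv <- opt$converged
  sol <- vc_profile(opt$par, design1, Kb, fit$components, "full")
  L1 <- -opt$value
  stat <- 2 * (L1 - fit$logLik)
  if (stat < -1e-6)
    warning("LRT statistic negative beyond tolerance (", format(stat), ")")
  stat <- max(stat, 0)
  eff <- sol$beta[length(sol$beta) - T_ + seq_len(T_)]
  names(eff) <- paste0("beta_", fit$traits)
  list(stat = stat, df = T_,
       p = stats::pchisq(stat, T_, lower.tail = FALSE),
       effects = eff, logLik_alt = L1, converged = conv)
}

# append the SNP's T columns to every design block
augment_design <- function(design, x, traits) {
  T_ <- design$T
  design$coef_names <- c(design$coef_names, paste0("snp:", traits))
  design$blocks <- lapply(design$blocks, function(b) {
    b$A <- cbind(b$A, snp_block(b, x[b$ids], T_))
    b
  })
  design
}

#' Genome scan: score test per SNP with LRT refinement of top hits
#'
#' Runs the score test for every SNP passing the MAF rule, refines the
#' \code{top_k} smallest score p-values (ties broken by genome order) with
#' the likelihood-ratio test, and attaches the number of SNPs tested, the
#' Bonferroni and Benjamini-Hochberg thresholds and the genomic inflation
#' factor.
#'
#' @param fit a \code{\link{pedvc}} null fit.
#' @param geno a \code{\link{geno_matrix}} covering the analyzed
#'   individuals (QC should already have been applied).
#' @param top_k number of top score hits to refine by LRT (default 10).
#' @param maf_min MAF threshold for testing (\code{NULL}: no filter);
#'   computed over the analyzed individuals.
#' @param maf_comparator \code{"lt"} skips MAF < maf_min, \code{"le"}
#'   skips MAF <= maf_min.
#' @param alpha family-wise error level for the Bonferroni threshold.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level.
#' @return an object of class \code{"pedvc_scan"}: a per-SNP table plus
#'   scan metadata (\code{m_tested}, \code{lambda_gc}, thresholds).
#' @export
gwas_scan <- function(fit, geno, top_k = 10L, maf_min = NULL,
                      maf_comparator = c("lt", "le"),
                      alpha = 0.05, fdr_q = 0.05) {
  stopifnot(inherits(fit, "pedvc"), inherits(geno, "geno_matrix"))
  maf_comparator <- match.arg(maf_comparator)
  ids <- fit$design$ids
  if (!all(ids %in% rownames(geno$dosage)))
    stop("genotypes missing for analyzed individual(s)")
  D <- geno$dosage[ids, , drop = FALSE]
  S <- ncol(D)
  maf <- apply(D, 2L, function(v) if (all(is.na(v))) NA_real_
               else minor_allele_frequency(v))
  founders <- intersect(fit$pedigree$person_id[fit$pedigree$founder], ids)
  hwe_p <- if (length(founders))
    apply(D[founders, , drop = FALSE], 2L, hwe_from_dosages)
    else rep(NA_real_, S)

  fail_maf <- if (is.null(maf_min)) rep(FALSE, S) else {
    if (maf_comparator == "lt") is.na(maf) | maf < maf_min
    else is.na(maf) | maf <= maf_min
  }
  tab <- data.frame(snp_id = geno$map$snp_id, chrom = geno$map$chrom,
                    bp = geno$map$bp, maf = maf, hwe_p = hwe_p,
                    score_stat = NA_real_, df = fit$T, score_p = NA_real_,
                    lrt_stat = NA_real_, lrt_p = NA_real_,
                    filter_flag = ifelse(fail_maf, "maf", ""),
                    stringsAsFactors = FALSE)
  test_idx <- which(!fail_maf)
  if (!length(test_idx))
    stop("no SNPs pass the MAF rule; empty scan")
  for (j in test_idx) {
    st <- score_test(fit, D[, j])
    if (st$flag != "ok") {
      tab$filter_flag[j] <- "undefined"
    } else {
      tab$score_stat[j] <- st$stat
      tab$score_p[j] <- st$p
    }
  }
  tested <- which(!is.na(tab$score_p))
  m_tested <- length(tested)
  if (!m_tested) stop("score test undefined for every SNP; empty scan")

  # refine top_k smallest score p (ties by genome order = column order)
  ord <- tested[order(tab$score_p[tested], tested)]
  refine <- utils::head(ord, top_k)
  effects <- list()
  for (j in refine) {
    lr <- lrt(fit, D[, j])
    if (!lr$converged) {
      tab$filter_flag[j] <- paste0(tab$filter_flag[j], "lrt_nonconv")
      next
    }
    tab$lrt_stat[j] <- lr$stat
    tab$lrt_p[j] <- lr$p
    effects[[tab$snp_id[j]]] <- lr$effects
  }
  eff_tab <- if (length(effects))
    data.frame(snp_id = names(effects),
               do.call(rbind, effects), row.names = NULL,
               check.names = FALSE)
    else NULL

  bf <- bonferroni_threshold(alpha, m_tested)
  fdr <- bh_fdr_threshold(tab$score_p[tested], fdr_q)
  lam <- genomic_inflation(tab$score_stat[tested], fit$T)
  structure(list(table = tab, m_tested = m_tested,
                 lambda_gc = lam, bonferroni = bf, fdr_cutoff = fdr,
                 alpha = alpha, fdr_q = fdr_q, top_k = top_k,
                 df = fit$T, effects = eff_tab,
                 maf_min = maf_min, maf_comparator = maf_comparator),
            class = "pedvc_scan")
}

#' @export
print.pedvc_scan <- function(x, ...) {
  cat(sprintf("Genome scan: %d SNPs tested (df = %d)\n", x$m_tested, x$df))
  cat(sprintf("  lambda_GC = %.3f\n", x$lambda_gc))
  cat(sprintf("  Bonferroni %.3g level: p < %.3g (-log10 = %.2f)\n",
              x$alpha, x$bonferroni$threshold, x$bonferroni$neg_log10))
  if (is.na(x$fdr_cutoff))
    cat(sprintf("  BH FDR %.3g: no discoveries\n", x$fdr_q))
  else
    cat(sprintf("  BH FDR %.3g cutoff: p <= %.3g\n", x$fdr_q, x$fdr_cutoff))
  top <- x$table[!is.na(x$table$lrt_p), , drop = FALSE]
  if (nrow(top)) {
    cat("  LRT-refined top hits:\n")
    print(utils::head(top[order(top$lrt_p),
                          c("snp_id", "maf", "score_p", "lrt_p")], 10L),
          row.names = FALSE)
  }
  invisible(x)
}

#' Genomic inflation factor
#'
#' \eqn{\lambda_{GC}} = median observed statistic / median of the
#' chi-square(df) distribution; values near 1 indicate calibrated tests.
#'
#' @param statistics test statistics (non-finite entries dropped).
#' @param df chi-square degrees of freedom.
#' @export
genomic_inflation <- function(statistics, df) {
  s <- statistics[is.finite(statistics)]
  if (!length(s)) stop("no finite statistics")
  stats::median(s) / stats::qchisq(0.5, df)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tests.
#' @return list with \code{threshold} = alpha / m and \code{neg_log10}
#'   (displayed to 2 decimals).
#' @examples
#' bonferroni_threshold(0.05, 3084046)  # 1.62e-8, -log10 = 7.79
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, m >= 1)
  list(threshold = alpha / m, neg_log10 = -log10(alpha / m))
}

#' Benjamini-Hochberg FDR p-value cutoff
#'
#' Step-up rule: the largest sorted p-value with
#' \eqn{p_{(i)} \le (i/m) q}; \code{NA} when nothing qualifies
#' (no discoveries).
#'
#' @param pvalues vector of p-values in [0, 1] (NAs dropped).
#' @param q FDR level.
#' @export
bh_fdr_threshold <- function(pvalues, q = 0.05) {
  p <- sort(pvalues[!is.na(pvalues)])
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (!m) return(NA_real_)
  ok <- which(p <= seq_len(m) / m * q)
  if (!length(ok)) NA_real_ else p[max(ok)]
}

#' Write scan results as TSV
#'
#' Tab-separated with columns snp_id, chrom, bp, maf, hwe_p, score_stat,
#' df, score_p, lrt_stat, lrt_p, filter_flag; numeric fields at full
#' precision so a read-back reproduces the scan table exactly.  Scan
#' metadata (m_tested, lambda_GC, thresholds) goes in '#'-prefixed header
#' lines.
#'
#' @param scan a \code{pedvc_scan}.
#' @param path output path.
#' @export
write_scan_results <- function(scan, path) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(m_tested = scan$m_tested, lambda_gc = scan$lambda_gc,
            bonferroni = scan$bonferroni$threshold,
            fdr_cutoff = scan$fdr_cutoff, df = scan$df,
            top_k = scan$top_k, alpha = scan$alpha, fdr_q = scan$fdr_q)
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, format(meta[[nm]], digits = 17)), con)
  tab <- scan$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a scan results TSV
#'
#' @param path file written by \code{\link{write_scan_results}}.
#' @return a \code{pedvc_scan} (without per-trait effect estimates).
#' @export
read_scan_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^#\\s*", "", l), "\\s*=\\s*")[[1L]]
    meta[[kv[1L]]] <- if (identical(kv[2L], "NA")) NA_real_
                      else as.numeric(kv[2L])
  }
  tab <- utils::read.table(text = lines[-hdr], sep = "\t", header = TRUE,
                           colClasses = c(snp_id = "character",
                                          chrom = "character",
                                          filter_flag = "character"),
                           na.strings = "", quote = "",
                           stringsAsFactors = FALSE)
  tab$filter_flag[is.na(tab$filter_flag)] <- ""
  structure(list(table = tab, m_tested = meta$m_tested,
                 lambda_gc = meta$lambda_gc,
                 bonferroni = list(threshold = meta$bonferroni,
                                   neg_log10 = -log10(meta$bonferroni)),
                 fdr_cutoff = if (is.null(meta$fdr_cutoff)) NA_real_
                              else meta$fdr_cutoff,
                 alpha = meta$alpha, fdr_q = meta$fdr_q,
                 top_k = meta$top_k, df = meta$df, effects = NULL,
                 maf_min = NULL, maf_comparator = NULL),
            class = "pedvc_scan")
}

#' Manhattan and Q-Q plots for a genome scan
#'
#' @param x a \code{pedvc_scan}.
#' @param which \code{"manhattan"}, \code{"qq"} or both.
#' @param ... passed to \code{plot}.
#' @export
plot.pedvc_scan <- function(x, which = c("manhattan", "qq"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  tab <- x$table[!is.na(x$table$score_p), , drop = FALSE]
  if (length(which) == 2L) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  if ("manhattan" %in% which) {
    chrf <- factor(tab$chrom, levels = unique(tab$chrom))
    off <- c(0, cumsum(tapply(as.numeric(tab$bp), chrf, max,
                              default = 0)))[as.integer(chrf)]
    graphics::plot(off + as.numeric(tab$bp), -log10(tab$score_p),
                   col = as.integer(chrf) %% 2L + 1L, pch = 20,
                   xlab = "genome position", ylab = "-log10 p", ...)
    graphics::abline(h = x$bonferroni$neg_log10, lty = 2)
  }
  if ("qq" %in% which) {
    obs <- sort(-log10(tab$score_p))
    exp <- sort(-log10(stats::ppoints(length(obs))))
    graphics::plot(exp, obs, pch = 20, xlab = "expected -log10 p",
                   ylab = "observed -log10 p", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
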