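#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the proportions expected under the observed allele frequency.
#' Expected-zero cells (monomorphic samples) contribute nothing when the
#' observed count is also zero, so a fixed locus returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (scalars or equal-length
#'   vectors).
#' @return p-value(s) of the chi-square test.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be non-negative")
  if (any(n == 0)) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  exp_counts <- cbind(n * p^2, n * 2 * p * (1 - p), n * (1 - p)^2)
  obs <- cbind(n_AA, n_Aa, n_aa)
  term <- (obs - exp_counts)^2 / exp_counts
  term[exp_counts == 0] <- ifelse(obs[exp_counts == 0] == 0, 0, Inf)
  chi2 <- rowSums(term)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Marker quality control
#'
#' Applies the three retention rules: call rate above `call_rate`, minor
#' allele frequency above `maf` in at least one breed, and no
#' Hardy-Weinberg departure at `hwe_p`. HWE is tested within each breed
#' cohort (pooling diverged breeds would produce a Wahlund heterozygote
#' deficit unrelated to genotyping quality); the reported `hwe_p` is the
#' minimum across breeds. Missing dosages surviving QC are mean-imputed
#' per SNP with a warning.
#'
#' @param panel A [genotype_panel()].
#' @param call_rate Minimum call rate, exclusive (default 0.99).
#' @param maf MAF threshold, exclusive (default 0.02).
#' @param hwe_p HWE p-value below which a SNP is excluded (default 1e-4).
#' @return A list with `panel` (filtered) and `report` (per-SNP
#'   data.frame with call_rate, per-breed MAF, hwe_p, pass and the first
#'   failing rule).
#' @export
apply_qc <- function(panel, call_rate = 0.99, maf = 0.02, hwe_p = 1e-4) {
  if (panel$n_snps == 0) stop("empty panel")
  dos <- panel$dosage
  breeds <- sort(unique(panel$breed))
  cr <- 1 - colMeans(is.na(dos))
  af <- panel_allele_freq(panel)
  maf_b <- pmin(af, 1 - af)
  hwe <- matrix(NA_real_, panel$n_snps, length(breeds),
                dimnames = list(panel$snp_ids, breeds))
  for (b in breeds) {
    db <- dos[panel$breed == b, , drop = FALSE]
    n2 <- colSums(db == 2, na.rm = TRUE)
    n1 <- colSums(db == 1, na.rm = TRUE)
    n0 <- colSums(db == 0, na.rm = TRUE)
    hwe[, b] <- hwe_test(n2, n1, n0)
  }
  hwe_min <- apply(hwe, 1, min)
  pass_cr <- cr > call_rate
  pass_maf <- apply(maf_b, 1, max, na.rm = TRUE) > maf
  pass_hwe <- hwe_min >= hwe_p
  pass <- pass_cr & pass_maf & pass_hwe
  fail_reason <- rep(NA_character_, panel$n_snps)
  fail_reason[!pass_hwe] <- "hwe"
  fail_reason[!pass_maf] <- "maf"
  fail_reason[!pass_cr] <- "call_rate"
  report <- data.frame(snp_id = panel$snp_ids, call_rate = cr,
                       stringsAsFactors = FALSE)
  for (b in breeds) report[[paste0("maf_", b)]] <- maf_b[, b]
  report$hwe_p <- hwe_min
  report$pass <- pass
  report$fail_reason <- fail_reason
  rownames(report) <- NULL
  if (!any(pass)) {
    stop("all ", panel$n_snps, " SNP removed by QC; ",
         "check thresholds against the panel")
  }
  kept <- panel_subset(panel, snps = which(pass))
  if (anyNA(kept$dosage)) {
    warning("mean-imputing ", sum(is.na(kept$dosage)),
            " missing dosages per SNP after QC")
    for (j in which(colSums(is.na(kept$dosage)) > 0)) {
      x <- kept$dosage[, j]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      kept$dosage[, j] <- x
    }
    kept$allele_freq <- panel_allele_freq(kept)
  }
  list(panel = kept, report = report)
}
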