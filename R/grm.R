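#' Genomic relationship matrix
#'
#' VanRaden-style GRM evaluated exactly as
#' `g_jk = (1/W) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' with `p_i` the observed alternate-allele frequency in the cohort the
#' panel holds and `W` the marker count entering the sum. The analysis is
#' within breed, so callers pass a single-breed subset
#' ([panel_subset_breed()]) and frequencies are the cohort's own.
#'
#' @param panel A [genotype_panel()], typically post-QC and single breed.
#' @param on_monomorphic What to do with SNP whose heterozygosity
#'   `2 p (1 - p)` falls below 1e-6 in this cohort: `"error"` (default)
#'   names the first offending SNP; `"drop"` excludes them with a warning
#'   and reduces `W` accordingly.
#' @return An object of class `grm`: list with `sample_ids`, `matrix`
#'   (symmetric samples x samples) and `n_snps_used`.
#' @export
compute_grm <- function(panel, on_monomorphic = c("error", "drop")) {
  on_monomorphic <- match.arg(on_monomorphic)
  X <- panel$dosage
  p <- colMeans(X) / 2
  het <- 2 * p * (1 - p)
  bad <- het < 1e-6
  if (any(bad)) {
    if (on_monomorphic == "error") {
      stop("monomorphic SNP in cohort (division by zero): ",
           panel$snp_ids[which(bad)[1]],
           if (sum(bad) > 1) paste0(" and ", sum(bad) - 1, " more"))
    }
    message("dropping ", sum(bad), " cohort-monomorphic SNP from the GRM")
    X <- X[, !bad, drop = FALSE]
    p <- p[!bad]
    het <- het[!bad]
  }
  W <- ncol(X)
  if (W == 0) stop("no usable SNP for the GRM")
  Z <- sweep(sweep(X, 2, 2 * p, `-`), 2, sqrt(het), `/`)
  G <- tcrossprod(Z) / W
  G <- (G + t(G)) / 2
  dimnames(G) <- list(panel$sample_ids, panel$sample_ids)
  structure(list(sample_ids = panel$sample_ids, matrix = G,
                 n_snps_used = W),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$sample_ids), "samples,", x$n_snps_used,
      "SNP; mean diagonal", round(mean(diag(x$matrix)), 3), "\n")
  invisible(x)
}
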