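#' Construct a genotype panel
#'
#' Container for a samples x SNP dosage matrix with marker metadata and
#' per-breed observed allele frequencies. Dosages count copies of the
#' alternate ("B") allele, so entries are 0, 1 or 2 (missing values are
#' only possible for user-supplied panels; the simulator emits complete
#' data).
#'
#' @param dosage Integer matrix, samples x SNP.
#' @param breed Character/factor of per-sample breed labels.
#' @param chrom Integer chromosome index per SNP.
#' @param pos Integer 1-based physical position (bp) per SNP; strictly
#'   increasing within each chromosome.
#' @param sample_ids,snp_ids Identifiers; defaults taken from dimnames.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, breed, chrom, pos,
                           sample_ids = rownames(dosage),
                           snp_ids = colnames(dosage)) {
  if (is.null(sample_ids)) sample_ids <- paste0("cow", seq_len(nrow(dosage)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(sample_ids, snp_ids)
  breed <- as.character(breed)
  stopifnot(length(breed) == nrow(dosage),
            length(chrom) == ncol(dosage),
            length(pos) == ncol(dosage))
  ord <- order(chrom, pos)
  if (!identical(ord, seq_along(pos))) {
    dosage <- dosage[, ord, drop = FALSE]
    chrom <- chrom[ord]
    pos <- pos[ord]
    snp_ids <- snp_ids[ord]
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must strictly increase within chromosome ", ch)
    }
  }
  panel <- structure(
    list(
      sample_ids = sample_ids,
      breed = breed,
      snp_ids = snp_ids,
      chrom = as.integer(chrom),
      pos = as.integer(pos),
      dosage = dosage,
      allele_freq = NULL,
      n_snps = ncol(dosage)
    ),
    class = "genotype_panel"
  )
  panel$allele_freq <- panel_allele_freq(panel)
  panel
}

#' Observed per-breed allele frequencies of a panel
#'
#' @param panel A [genotype_panel()].
#' @return SNP x breed matrix of observed alternate-allele frequencies
#'   (`p_i`), computed from the dosage matrix (missing entries ignored).
#' @export
panel_allele_freq <- function(panel) {
  breeds <- sort(unique(panel$breed))
  af <- vapply(breeds, function(b) {
    colMeans(panel$dosage[panel$breed == b, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(panel$n_snps))
  af <- matrix(af, nrow = panel$n_snps,
               dimnames = list(panel$snp_ids, breeds))
  af
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x", x$n_snps,
      "SNP\n")
  cat("  breeds:",
      paste(sprintf("%s (%d)", names(table(x$breed)), table(x$breed)),
            collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$chrom)), "\n")
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel A [genotype_panel()].
#' @param samples,snps Logical/integer/character index into samples or SNP
#'   (default keep all). Allele frequencies are recomputed on the subset.
#' @return A [genotype_panel()].
#' @export
panel_subset <- function(panel, samples = NULL, snps = NULL) {
  d <- panel$dosage
  br <- panel$breed
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, panel$sample_ids)
    d <- d[samples, , drop = FALSE]
    br <- br[samples]
  }
  ch <- panel$chrom
  po <- panel$pos
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, panel$snp_ids)
    d <- d[, snps, drop = FALSE]
    ch <- ch[snps]
    po <- po[snps]
  }
  genotype_panel(d, br, ch, po)
}

#' @rdname panel_subset
#' @param breed Breed label to keep.
#' @export
panel_subset_breed <- function(panel, breed) {
  panel_subset(panel, samples = panel$breed == breed)
}

#' Simulate multi-breed SNP genotypes
#'
#' Draws a shared ancestral alternate-allele frequency per SNP uniformly
#' from `maf_range`, perturbs it independently per breed with a
#' Beta(p(1-F)/F, (1-p)(1-F)/F) draw (Balding-Nichols style divergence
#' with a single F-like parameter), and samples dosages binomially per
#' animal, giving within-breed Hardy-Weinberg proportions. Loci are
#' independent (no linkage disequilibrium); positions are uniform within
#' chromosomes.
#'
#' @param n_per_breed Integer vector of cohort sizes, one per breed
#'   (breeds labelled A, B, C, ... in order).
#' @param n_snps Total marker count across `n_chrom` chromosomes.
#' @param n_chrom Number of autosomes (default 5).
#' @param maf_range Interval within (0, 0.5] for the ancestral frequency
#'   (default `c(0.02, 0.5)`, a near-uniform spectrum as on dairy SNP
#'   chips retained for genomic evaluation).
#' @param fst Breed-divergence parameter in \[0, 1); 0 disables
#'   divergence.
#' @param chrom_length Length of each chromosome in bp.
#' @param seed Integer seed; the same inputs and seed give a bit-identical
#'   panel.
#' @return A [genotype_panel()] with an `ancestral_freq` attribute.
#' @export
simulate_genotypes <- function(n_per_breed, n_snps, n_chrom = 5,
                               maf_range = c(0.02, 0.5), fst = 0.05,
                               chrom_length = 2e7, seed = 1) {
  if (any(n_per_breed <= 0)) stop("cohort sizes must be positive")
  if (length(maf_range) != 2 || diff(maf_range) < 0) {
    stop("maf_range must be an interval c(lo, hi)")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (n_snps < n_chrom) stop("need at least one SNP per chromosome")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  breeds <- LETTERS[seq_along(n_per_breed)]

  withr::with_seed(seed, {
    # positions: spread SNP over chromosomes as evenly as possible
    per_chrom <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
    chrom <- rep(seq_len(n_chrom), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k) {
      sort(sample.int(chrom_length, k))
    }))
    p_anc <- stats::runif(n_snps, maf_range[1], maf_range[2])
    dos <- matrix(NA_integer_, sum(n_per_breed), n_snps)
    row0 <- 0L
    for (bi in seq_along(breeds)) {
      nb <- n_per_breed[bi]
      if (fst > 0) {
        p_b <- stats::rbeta(n_snps,
                            p_anc * (1 - fst) / fst,
                            (1 - p_anc) * (1 - fst) / fst)
      } else {
        p_b <- p_anc
      }
      dos[row0 + seq_len(nb), ] <- matrix(
        stats::rbinom(nb * n_snps, 2L, rep(p_b, each = nb)), nb, n_snps)
      row0 <- row0 + nb
    }
    breed <- rep(breeds, n_per_breed)
    rownames(dos) <- paste0("cow_", breed, "_",
                            unlist(lapply(n_per_breed, seq_len)))
    colnames(dos) <- sprintf("snp%05d", seq_len(n_snps))
    panel <- genotype_panel(dos, breed, chrom, pos)
    attr(panel, "ancestral_freq") <- p_anc
    panel
  })
}

#' Simulate a non-overlapping gene map
#'
#' Genes are allocated to chromosomes proportionally to length, given
#' exponential lengths with the requested mean (floored at `min_length`),
#' and placed without overlap by distributing the free space uniformly at
#' random between consecutive genes. Because placement never stacks
#' genes, the fraction of the genome within `window` bp of a gene is
#' controlled by gene count and length; [gene_coverage_fraction()] gives
#' its exact value and [genes_for_coverage()] the count needed for a
#' target fraction.
#'
#' @param n_genes Total number of genes (0 gives an empty map).
#' @param chrom_lengths Numeric vector of chromosome lengths in bp.
#' @param mean_gene_length Mean gene length in bp.
#' @param seed Integer seed.
#' @param min_length Minimum gene length in bp (default 200).
#' @return A `gene_map` data.frame with columns gene_id, chrom, start,
#'   end (1-based inclusive), strand; sorted by (chrom, start).
#' @export
simulate_gene_map <- function(n_genes, chrom_lengths,
                              mean_gene_length = 15000, seed = 1,
                              min_length = 200) {
  stopifnot(n_genes >= 0, all(chrom_lengths > 0))
  empty <- data.frame(gene_id = character(), chrom = integer(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  class(empty) <- c("gene_map", "data.frame")
  if (n_genes == 0) return(empty)
  if (sum(chrom_lengths) < n_genes * mean_gene_length) {
    stop("infeasible packing: total chromosome length ",
         sum(chrom_lengths), " < ", n_genes, " x ", mean_gene_length)
  }
  withr::with_seed(seed, {
    share <- n_genes * chrom_lengths / sum(chrom_lengths)
    n_c <- floor(share)
    rem <- n_genes - sum(n_c)
    if (rem > 0) {
      top <- order(share - n_c, decreasing = TRUE)[seq_len(rem)]
      n_c[top] <- n_c[top] + 1
    }
    out <- vector("list", length(chrom_lengths))
    gid <- 0L
    for (ci in seq_along(chrom_lengths)) {
      k <- n_c[ci]
      if (k == 0) next
      len <- pmax(min_length, round(stats::rexp(k, 1 / mean_gene_length)))
      # retry once with shrunken draws if the exponential tail overpacks
      if (sum(len) >= chrom_lengths[ci]) {
        len <- pmax(min_length,
                    round(len * 0.9 * chrom_lengths[ci] / sum(len)))
      }
      if (sum(len) >= chrom_lengths[ci]) {
        stop("infeasible packing on chromosome ", ci)
      }
      free <- chrom_lengths[ci] - sum(len)
      cuts <- floor(sort(stats::runif(k)) * free)
      start <- cuts + c(0, cumsum(len[-k])) + 1
      end <- start + len - 1
      out[[ci]] <- data.frame(
        gene_id = sprintf("G%04d", gid + seq_len(k)),
        chrom = ci, start = as.integer(start), end = as.integer(end),
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
      gid <- gid + k
    }
    gm <- do.call(rbind, out)
    rownames(gm) <- NULL
    class(gm) <- c("gene_map", "data.frame")
    gm
  })
}

#' Exact genome fraction within a window of any gene
#'
#' Closed-form coverage of the union of `[start - window, end + window]`
#' intervals (clipped to chromosome bounds), as a fraction of the total
#' genome length. This is the expected fraction of uniformly placed SNP
#' falling within `window` bp of a gene.
#'
#' @param genes A gene map data.frame (gene_id, chrom, start, end).
#' @param chrom_lengths Chromosome lengths in bp (indexed by chromosome).
#' @param window Padding in bp (default 10000).
#' @return Fraction in \[0, 1\].
#' @export
gene_coverage_fraction <- function(genes, chrom_lengths, window = 10000) {
  total <- sum(chrom_lengths)
  if (nrow(genes) == 0) return(0)
  covered <- 0
  for (ci in unique(genes$chrom)) {
    g <- genes[genes$chrom == ci, , drop = FALSE]
    s <- pmax(1, g$start - window)
    e <- pmin(chrom_lengths[ci], g$end + window)
    o <- order(s)
    s <- s[o]; e <- e[o]
    cur_s <- s[1]; cur_e <- e[1]
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] <= cur_e + 1) {
          cur_e <- max(cur_e, e[i])
        } else {
          covered <- covered + (cur_e - cur_s + 1)
          cur_s <- s[i]; cur_e <- e[i]
        }
      }
    }
    covered <- covered + (cur_e - cur_s + 1)
  }
  covered / total
}

#' @rdname gene_coverage_fraction
#' @param target Desired coverage fraction.
#' @param mean_gene_length Mean gene length in bp.
#' @return `genes_for_coverage()`: approximate gene count achieving the
#'   target fraction (ignoring pad overlap, so slightly conservative).
#' @export
genes_for_coverage <- function(target, chrom_lengths,
                               mean_gene_length = 15000, window = 10000) {
  stopifnot(target > 0, target < 1)
  round(target * sum(chrom_lengths) / (mean_gene_length + 2 * window))
}

#' Simulate correlated multi-trait phenotypes with known truth
#'
#' A sparse pleiotropic architecture: `n_causal` SNP are drawn without
#' replacement and receive effect vectors from a multivariate normal with
#' covariance proportional to `target_corr`, so the same loci drive all
#' traits and trait genetic values are correlated. Genetic values are
#' `dosage %*% effects` (dosage centred per locus); residuals are drawn
#' with cross-trait correlation `resid_corr` (defaulting to
#' `target_corr`: yield deviations on the same cows share environmental
#' covariance tracking the genetic one) and scaled so the realized
#' variance ratio matches `target_h2` per trait. Clinical mastitis (CM)
#' is produced by thresholding its latent liability at the empirical
#' quantile giving `cm_incidence` cases.
#'
#' @param panel A [genotype_panel()].
#' @param n_causal Number of causal SNP.
#' @param target_corr 12 x 12 genetic correlation target (default
#'   [default_genetic_corr()]); must be a valid correlation matrix.
#' @param target_h2 Per-trait heritability targets in (0, 1) (default
#'   [default_h2()]).
#' @param resid_corr Residual cross-trait correlation matrix; `NULL`
#'   (default) reuses `target_corr`; pass `diag(12)` for independent
#'   residuals.
#' @param cm_incidence Fraction of cows scored 1 for CM (default 0.25).
#' @param cm_binary Threshold CM to 0/1 (default TRUE); FALSE keeps the
#'   continuous liability (useful for calibration checks).
#' @param seed Integer seed.
#' @return A list with components `traits` (a `trait_table`) and `truth`
#'   (a `truth_set` holding causal SNP ids, the causal-SNP x trait effect
#'   matrix, the target correlation/heritability, the per-cow genetic
#'   values and the CM latent liability).
#' @export
simulate_phenotypes <- function(panel, n_causal,
                                target_corr = default_genetic_corr(),
                                target_h2 = default_h2(),
                                resid_corr = NULL,
                                cm_incidence = 0.25, cm_binary = TRUE,
                                seed = 1) {
  traits <- trait_names()
  stopifnot(is.matrix(target_corr),
            nrow(target_corr) == length(traits),
            ncol(target_corr) == length(traits))
  if (!is.null(rownames(target_corr)) &&
      !identical(rownames(target_corr), traits)) {
    target_corr <- target_corr[traits, traits]
  }
  if (max(abs(target_corr - t(target_corr))) > 1e-8 ||
      max(abs(diag(target_corr) - 1)) > 1e-8) {
    stop("target_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("target_corr is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3),
         "); see nearest_correlation()")
  }
  if (n_causal < 1 || n_causal > panel$n_snps) {
    stop("n_causal must be in [1, n_snps]")
  }
  if (length(target_h2) != length(traits)) {
    stop("target_h2 must have one entry per trait")
  }
  if (any(target_h2 <= 0) || any(target_h2 >= 1)) {
    stop("target_h2 entries must be in (0, 1)")
  }
  if (is.null(resid_corr)) resid_corr <- target_corr
  n <- length(panel$sample_ids)

  withr::with_seed(seed, {
    causal <- sort(sample.int(panel$n_snps, n_causal))
    causal_ids <- panel$snp_ids[causal]
    L <- chol(nearest_correlation(target_corr))
    B <- matrix(stats::rnorm(n_causal * length(traits)), n_causal) %*% L
    dimnames(B) <- list(causal_ids, traits)
    Xc <- scale(panel$dosage[, causal, drop = FALSE], center = TRUE,
                scale = FALSE)
    G <- Xc %*% B
    colnames(G) <- traits
    Lr <- chol(nearest_correlation(resid_corr))
    E <- matrix(stats::rnorm(n * length(traits)), n) %*% Lr
    E <- scale(E)  # exact zero mean / unit sd per column
    var_g <- apply(G, 2, stats::var)
    if (any(var_g <= 0)) stop("degenerate genetic values; increase n_causal")
    sd_e <- sqrt(var_g * (1 - target_h2) / target_h2)
    Y <- G + sweep(E, 2, sd_e, `*`)
    Y <- matrix(as.numeric(Y), nrow = n,
                dimnames = list(panel$sample_ids, traits))
    cm_latent <- Y[, "CM"]
    cm_threshold <- NA_real_
    if (cm_binary) {
      cm_threshold <- stats::quantile(cm_latent, 1 - cm_incidence,
                                      names = FALSE)
      Y[, "CM"] <- as.numeric(cm_latent > cm_threshold)
    }
    tt <- structure(
      list(sample_ids = panel$sample_ids,
           trait_names = traits,
           values = Y,
           trait_role = trait_roles()),
      class = "trait_table")
    truth <- structure(
      list(causal_snp_ids = causal_ids,
           true_effects = B,
           true_genetic_corr = target_corr,
           true_h2 = stats::setNames(as.numeric(target_h2), traits),
           genetic_values = G,
           cm_latent = cm_latent,
           cm_threshold = cm_threshold,
           seed = seed),
      class = "truth_set")
    list(traits = tt, truth = truth)
  })
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$sample_ids), "cows x",
      length(x$trait_names), "traits\n")
  invisible(x)
}

#' Realized heritability and genetic correlations from stored truth
#'
#' `realized_h2()` is the squared correlation between stored genetic
#' values and phenotypes (CM evaluated on the latent liability when it
#' was binarized); `realized_genetic_corr()` is the correlation matrix of
#' the genetic values across cows.
#'
#' @param traits A `trait_table` from [simulate_phenotypes()].
#' @param truth The matching `truth_set`.
#' @return Named per-trait vector / trait x trait matrix.
#' @export
realized_h2 <- function(traits, truth) {
  Y <- traits$values
  if (!is.na(truth$cm_threshold)) Y[, "CM"] <- truth$cm_latent
  vapply(colnames(Y),
         function(t) stats::cor(truth$genetic_values[, t], Y[, t])^2,
         numeric(1))
}

#' @rdname realized_h2
#' @export
realized_genetic_corr <- function(truth) {
  stats::cor(truth$genetic_values)
}

#' Somatic cell score from somatic cell count
#'
#' The standard log transform `SCS = 3 + log2(SCC / 100000)` with SCC in
#' cells per mL: 100,000 cells/mL maps to score 3 and every doubling adds
#' one point. Exactly invertible via [scc_from_scs()].
#'
#' @param scc Somatic cell count (cells/mL), positive.
#' @return Somatic cell score.
#' @export
scs_from_scc <- function(scc) {
  if (any(scc <= 0)) stop("scc must be positive")
  3 + log2(scc / 1e5)
}

#' @rdname scs_from_scc
#' @param scs Somatic cell score.
#' @export
scc_from_scs <- function(scs) {
  1e5 * 2^(scs - 3)
}

#' Heritability of a yield deviation
#'
#' A yield deviation averages `n_records` records that were already
#' adjusted for permanent environment, so its residual variance shrinks
#' by the record count while the additive variance does not:
#' `h2_YD = va / (va + vr / n)`. Monotone increasing in `n` with limit 1.
#'
#' @param var_additive Additive genetic variance (> 0).
#' @param var_residual Residual variance of a single record (> 0).
#' @param n_records Average number of records per cow (>= 1).
#' @return Heritability of the yield deviation.
#' @export
yd_heritability <- function(var_additive, var_residual, n_records) {
  if (any(var_additive <= 0) || any(var_residual <= 0)) {
    stop("variances must be positive")
  }
  if (any(n_records < 1)) stop("n_records must be >= 1")
  var_additive / (var_additive + var_residual / n_records)
}
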