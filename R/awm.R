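#' Align per-trait association results into effect and p-value matrices
#'
#' @param assoc_list Named list of `assoc_result` data.frames (one per
#'   trait, same panel).
#' @return List with `effect` and `p` (SNP x trait matrices, rownames =
#'   snp ids), plus `chrom` and `pos` vectors.
#' @export
assoc_matrices <- function(assoc_list) {
  stopifnot(length(assoc_list) >= 1)
  ids <- assoc_list[[1]]$snp_id
  eff <- vapply(assoc_list, function(a) {
    a$effect[match(ids, a$snp_id)]
  }, numeric(length(ids)))
  p <- vapply(assoc_list, function(a) {
    a$p_raw[match(ids, a$snp_id)]
  }, numeric(length(ids)))
  dimnames(eff) <- dimnames(p) <- list(ids, names(assoc_list))
  list(effect = eff, p = p,
       chrom = assoc_list[[1]]$chrom, pos = assoc_list[[1]]$pos)
}

#' z-score allele-substitution effects per trait
#'
#' Column-wise standardization of the effects of all tested SNP within a
#' breed: deviate from the column mean and divide by the column standard
#' deviation (population convention, i.e. divisor `n`), so every AWM cell
#' is on a common scale regardless of the trait's measurement units.
#'
#' @param effects SNP x trait matrix of allele-substitution effects.
#' @return Matrix of the same shape with zero-mean, unit-SD columns.
#' @export
zscore_effects <- function(effects) {
  stopifnot(is.matrix(effects), nrow(effects) >= 2)
  z <- apply(effects, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    s <- sqrt(mean((x - mu)^2, na.rm = TRUE))
    if (!is.finite(s) || s == 0) stop("constant effect column")
    (x - mu) / s
  })
  dimnames(z) <- dimnames(effects)
  z
}

#' AWM step 1: primary SNP selection on the key trait
#'
#' @param p SNP x trait matrix of raw GWAS p-values.
#' @param key_trait Key trait column name (default "UDD").
#' @param alpha Nominal threshold (default 0.05); SNP with key-trait
#'   p < alpha are selected. Missing p-values never select.
#' @return Character vector of selected SNP ids.
#' @export
select_primary <- function(p, key_trait = "UDD", alpha = 0.05) {
  if (!key_trait %in% colnames(p)) stop("unknown key trait: ", key_trait)
  sel <- !is.na(p[, key_trait]) & p[, key_trait] < alpha
  rownames(p)[sel]
}

#' AWM step 2: average number of associated non-key traits
#'
#' For each selected SNP, counts the non-key traits with p < alpha and
#' returns the mean count. Its rounded value is the data-driven default
#' for the step-3 pleiotropy threshold.
#'
#' @param selected SNP ids from [select_primary()].
#' @param p SNP x trait p-value matrix.
#' @inheritParams select_primary
#' @return Mean count (numeric scalar) with attribute `per_snp`, the
#'   named per-SNP counts.
#' @export
count_dependencies <- function(selected, p, key_trait = "UDD",
                               alpha = 0.05) {
  if (length(selected) == 0) stop("no selected SNP")
  other <- setdiff(colnames(p), key_trait)
  sig <- !is.na(p[selected, other, drop = FALSE]) &
    p[selected, other, drop = FALSE] < alpha
  cnt <- rowSums(sig)
  out <- mean(cnt)
  attr(out, "per_snp") <- cnt
  out
}

#' AWM step 3: secondary selection of pleiotropic SNP
#'
#' From the primary set (or, with `from_all = TRUE`, the original
#' rescue variant scanning every tested SNP), keeps SNP associated with
#' at least `min_other` non-key traits of which at least `min_udder` are
#' non-key udder conformation traits.
#'
#' @param p SNP x trait p-value matrix.
#' @param primary SNP ids from [select_primary()]; recomputed when NULL.
#' @param min_other Minimum non-key associations; defaults to the rounded
#'   [count_dependencies()] value on the primary set.
#' @param min_udder Minimum non-key udder-trait associations (default 2).
#' @param from_all Scan all SNP instead of the primary set (default
#'   FALSE).
#' @inheritParams select_primary
#' @return Character vector of selected SNP ids, with attribute
#'   `min_other` recording the threshold used.
#' @export
select_secondary <- function(p, primary = NULL, key_trait = "UDD",
                             alpha = 0.05, min_other = NULL,
                             min_udder = 2, from_all = FALSE) {
  if (is.null(primary)) primary <- select_primary(p, key_trait, alpha)
  if (is.null(min_other)) {
    min_other <- round(as.numeric(count_dependencies(primary, p,
                                                     key_trait, alpha)))
  }
  pool <- if (from_all) rownames(p) else primary
  other <- setdiff(colnames(p), key_trait)
  udder_other <- setdiff(intersect(udder_traits(), colnames(p)), key_trait)
  sig <- !is.na(p[pool, , drop = FALSE]) & p[pool, , drop = FALSE] < alpha
  n_other <- rowSums(sig[, other, drop = FALSE])
  n_udder <- rowSums(sig[, udder_other, drop = FALSE])
  out <- pool[n_other >= min_other & n_udder >= min_udder]
  attr(out, "min_other") <- min_other
  out
}

#' AWM step 4a: assign SNP to genes by proximity
#'
#' Each SNP is classified as `in_gene` (position inside a gene interval,
#' distance 0), `within_10kb` (gap of 1..window bp to the nearest gene,
#' boundary inclusive) or `beyond_10kb` (gap > window, or no gene on the
#' chromosome). Distance is the bp gap between the SNP position and the
#' nearest interval edge on the same chromosome; equidistant ties go to
#' the gene with the lower start.
#'
#' @param snp_id,chrom,pos Parallel vectors of SNP identifiers and
#'   coordinates (1-based).
#' @param genes A gene map data.frame (gene_id, chrom, start, end),
#'   non-overlapping within chromosome.
#' @param window Proximity window in bp (default 10000).
#' @return Data.frame snp_id, category, nearest_gene_id (NA when no gene
#'   on the chromosome), distance_bp (NA likewise).
#' @export
annotate_snps <- function(snp_id, chrom, pos, genes, window = 10000) {
  n <- length(snp_id)
  stopifnot(length(chrom) == n, length(pos) == n)
  cat_out <- rep("beyond_10kb", n)
  gene_out <- rep(NA_character_, n)
  dist_out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    si <- which(chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$start), , drop = FALSE]
    idx <- findInterval(pos[si], g$start)
    # candidate 1: last gene starting at or before the SNP
    d1 <- rep(Inf, length(si))
    ok1 <- idx >= 1
    d1[ok1] <- pmax(0, pos[si][ok1] - g$end[idx[ok1]])
    # candidate 2: first gene starting after the SNP
    d2 <- rep(Inf, length(si))
    ok2 <- idx < nrow(g)
    d2[ok2] <- g$start[idx[ok2] + 1] - pos[si][ok2]
    # ties (d1 == d2) go to the lower-start gene, i.e. candidate 1
    use1 <- d1 <= d2
    best_gene <- ifelse(use1, g$gene_id[pmax(idx, 1)],
                        g$gene_id[pmin(idx + 1, nrow(g))])
    best_d <- pmin(d1, d2)
    gene_out[si] <- best_gene
    dist_out[si] <- best_d
    cat_out[si] <- ifelse(best_d == 0, "in_gene",
                          ifelse(best_d <= window, "within_10kb",
                                 "beyond_10kb"))
  }
  data.frame(snp_id = snp_id, category = cat_out,
             nearest_gene_id = gene_out, distance_bp = dist_out,
             stringsAsFactors = FALSE)
}

#' AWM step 4b: one SNP per gene
#'
#' Among gene-assigned candidates (`in_gene` or `within_10kb`) sharing a
#' gene, keeps the SNP associated with the highest number of traits
#' (p < alpha over all trait columns); ties are broken by the lowest mean
#' raw p-value across all traits, then by the smallest position.
#' `beyond_10kb` candidates carry no gene key and are never deduplicated.
#'
#' @param candidates SNP ids to deduplicate.
#' @param annotation [annotate_snps()] output covering the candidates.
#' @param p SNP x trait p-value matrix.
#' @param pos Named (by snp id) or panel-ordered position vector used for
#'   the final tie-break; a named vector is safest.
#' @param alpha Threshold defining "associated" (default 0.05).
#' @return Character vector: kept SNP ids (gene representatives plus all
#'   beyond_10kb candidates).
#' @export
dedupe_per_gene <- function(candidates, annotation, p, pos,
                            alpha = 0.05) {
  ann <- annotation[match(candidates, annotation$snp_id), , drop = FALSE]
  if (anyNA(ann$snp_id)) stop("annotation missing for some candidates")
  if (is.null(names(pos))) names(pos) <- rownames(p)
  gene_assigned <- ann$category %in% c("in_gene", "within_10kb")
  keep <- candidates[!gene_assigned]
  if (any(gene_assigned)) {
    cand <- candidates[gene_assigned]
    gene <- ann$nearest_gene_id[gene_assigned]
    sig <- !is.na(p[cand, , drop = FALSE]) & p[cand, , drop = FALSE] < alpha
    n_traits <- rowSums(sig)
    mean_p <- rowMeans(p[cand, , drop = FALSE], na.rm = TRUE)
    po <- pos[cand]
    for (g in unique(gene)) {
      i <- which(gene == g)
      best <- i[order(-n_traits[i], mean_p[i], po[i])][1]
      keep <- c(keep, cand[best])
    }
  }
  keep[order(match(keep, candidates))]
}

#' Build the Association Weight Matrix for one breed
#'
#' Runs the five AWM steps on a breed's per-trait association results:
#' (1) primary selection on the key trait at `alpha`; (2) the average
#' non-key dependency count; (3) secondary (pleiotropy) selection at
#' `min_other`/`min_udder`; (4) gene annotation of the candidate SNP with
#' one-SNP-per-gene deduplication of the gene-assigned class (set1),
#' keeping intergenic candidates as set2; (5) the matrix of z-scored
#' allele-substitution effects (standardized over all tested SNP, then
#' row-restricted) for all 12 traits. Candidate rows are the primary set;
#' rows also passing the step-3 filter carry provenance
#' `selection_step = "secondary"` (with `secondary_from_all = TRUE`,
#' step 3 scans every tested SNP and can add rows beyond the primary
#' set).
#'
#' @param assoc_list Named list of per-trait `assoc_result` data.frames.
#' @param genes Gene map data.frame.
#' @param key_trait,alpha,min_other,min_udder,window See the step
#'   functions.
#' @param secondary_from_all Step-3 rescue over all SNP (default FALSE).
#' @param breed Label stored on the result.
#' @return An object of class `awm`: list with `z` (rows x traits matrix,
#'   rownames = gene id for set1 rows, snp id for set2 rows),
#'   `provenance` (per-row data.frame: snp_id, row_label, gene_id,
#'   category, distance_bp, selection_step, n_traits_associated, mean_p,
#'   chrom, pos) and `counts` (stage attrition).
#' @export
build_awm <- function(assoc_list, genes, key_trait = "UDD", alpha = 0.05,
                      min_other = NULL, min_udder = 2, window = 10000,
                      secondary_from_all = FALSE,
                      breed = NA_character_) {
  m <- assoc_matrices(assoc_list)
  z <- zscore_effects(m$effect)
  primary <- select_primary(m$p, key_trait, alpha)
  if (length(primary) == 0) {
    stop("empty AWM: no SNP passed primary selection (",
         nrow(m$p), " tested, alpha = ", alpha, ")")
  }
  dep <- count_dependencies(primary, m$p, key_trait, alpha)
  secondary <- select_secondary(m$p, primary, key_trait, alpha,
                                min_other, min_udder,
                                from_all = secondary_from_all)
  min_other_used <- attr(secondary, "min_other")
  candidates <- union(primary, as.character(secondary))
  candidates <- candidates[order(match(candidates, rownames(m$p)))]
  ann <- annotate_snps(rownames(m$p), m$chrom, m$pos, genes, window)
  pos_named <- stats::setNames(m$pos, rownames(m$p))
  kept <- dedupe_per_gene(candidates, ann, m$p, pos_named, alpha)
  if (length(kept) == 0) {
    stop("empty AWM after deduplication (primary = ", length(primary),
         ", candidates = ", length(candidates), ")")
  }
  ann_k <- ann[match(kept, ann$snp_id), , drop = FALSE]
  set1 <- ann_k$category %in% c("in_gene", "within_10kb")
  sig <- !is.na(m$p[kept, , drop = FALSE]) &
    m$p[kept, , drop = FALSE] < alpha
  prov <- data.frame(
    snp_id = kept,
    row_label = ifelse(set1, ann_k$nearest_gene_id, kept),
    gene_id = ifelse(set1, ann_k$nearest_gene_id, NA_character_),
    category = ann_k$category,
    distance_bp = ann_k$distance_bp,
    selection_step = ifelse(kept %in% secondary, "secondary", "primary"),
    n_traits_associated = rowSums(sig),
    mean_p = rowMeans(m$p[kept, , drop = FALSE], na.rm = TRUE),
    chrom = m$chrom[match(kept, rownames(m$p))],
    pos = m$pos[match(kept, rownames(m$p))],
    stringsAsFactors = FALSE)
  ord <- order(prov$chrom, prov$pos)
  prov <- prov[ord, , drop = FALSE]
  rownames(prov) <- NULL
  zmat <- z[prov$snp_id, , drop = FALSE]
  rownames(zmat) <- prov$row_label
  counts <- c(n_tested = nrow(m$p),
              n_primary = length(primary),
              mean_dependency = round(as.numeric(dep), 3),
              min_other = min_other_used,
              n_secondary = length(secondary),
              n_gene_assigned = sum(ann$category[
                match(candidates, ann$snp_id)] != "beyond_10kb"),
              set1 = sum(set1), set2 = sum(!set1),
              rows = nrow(prov))
  structure(list(z = zmat, provenance = prov, counts = counts,
                 key_trait = key_trait, alpha = alpha, breed = breed),
            class = "awm")
}

#' @export
print.awm <- function(x, ...) {
  cat("awm (breed ", x$breed, "): ", nrow(x$z), " rows x ",
      ncol(x$z), " traits (set1 = ", x$counts[["set1"]],
      ", set2 = ", x$counts[["set2"]], ")\n", sep = "")
  invisible(x)
}

#' SNP-based trait correlations from an AWM
#'
#' Pearson correlations between trait columns over the AWM rows; the
#' column-wise analogue of genetic correlations, computable from GWAS
#' effects alone.
#'
#' @param awm An [build_awm()] result (or a rows x traits matrix).
#' @return Symmetric trait x trait correlation matrix.
#' @export
awm_trait_correlations <- function(awm) {
  z <- if (inherits(awm, "awm")) awm$z else awm
  if (nrow(z) < 3) stop("need at least 3 AWM rows")
  sds <- apply(z, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column in AWM: ",
         paste(colnames(z)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(z)
  (R + t(R)) / 2
}

#' Multi-breed overlap of AWM SNP sets
#'
#' Venn decomposition of the per-breed AWM row SNP sets: all seven
#' regions plus the three-way intersection used downstream, and the gene
#' set the common SNP map to.
#'
#' @param awm_list Named list of three `awm` objects (or character
#'   vectors of SNP ids).
#' @return List with `counts` (named seven-region + pairwise + common
#'   counts), `common_snp_ids` and `common_gene_ids`.
#' @export
combine_breeds <- function(awm_list) {
  stopifnot(length(awm_list) == 3)
  ids <- lapply(awm_list, function(a) {
    if (inherits(a, "awm")) a$provenance$snp_id else as.character(a)
  })
  if (is.null(names(ids)) || any(names(ids) == "")) {
    names(ids) <- LETTERS[1:3]
  }
  A <- ids[[1]]; B <- ids[[2]]; C <- ids[[3]]
  abc <- Reduce(intersect, ids)
  ab <- intersect(A, B); ac <- intersect(A, C); bc <- intersect(B, C)
  counts <- c(
    only_A = length(setdiff(A, union(B, C))),
    only_B = length(setdiff(B, union(A, C))),
    only_C = length(setdiff(C, union(A, B))),
    AB_only = length(setdiff(ab, abc)),
    AC_only = length(setdiff(ac, abc)),
    BC_only = length(setdiff(bc, abc)),
    ABC = length(abc),
    pair_AB = length(ab), pair_AC = length(ac), pair_BC = length(bc),
    union = length(Reduce(union, ids)))
  names(counts)[1:3] <- paste0("only_", names(ids))
  common_genes <- character()
  if (length(abc) > 0 && inherits(awm_list[[1]], "awm")) {
    pr <- awm_list[[1]]$provenance
    common_genes <- sort(unique(stats::na.omit(
      pr$gene_id[pr$snp_id %in% abc])))
  }
  structure(list(counts = counts, common_snp_ids = abc,
                 common_gene_ids = common_genes),
            class = "breed_overlap")
}

#' @export
print.breed_overlap <- function(x, ...) {
  cat("breed_overlap:", x$counts[["ABC"]], "SNP common to all three breeds",
      "mapping", length(x$common_gene_ids), "genes\n")
  invisible(x)
}
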