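#' Write a genotype panel as a minimal VCF
#'
#' VCFv4.2 with GT as the only FORMAT field; the counted (dosage) allele
#' is the ALT allele, so dosage 0/1/2 maps to 0/0, 0/1, 1/1 and missing
#' dosages to ./. . REF/ALT are placeholder A/B alleles (the simulator
#' does not model nucleotide identity).
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @param chrom_length Contig length written in the header (single value
#'   recycled per chromosome).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, chrom_length = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=awmpcit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  for (ch in sort(unique(panel$chrom))) {
    len <- if (is.null(chrom_length)) max(panel$pos[panel$chrom == ch]) + 1
           else chrom_length
    writeLines(sprintf("##contig=<ID=%d,length=%d>", ch, as.integer(len)),
               con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", panel$sample_ids),
                   collapse = "\t"), con)
  gt <- matrix(".\\.", length(panel$sample_ids), panel$n_snps)
  gt[] <- c("0/0", "0/1", "1/1")[panel$dosage + 1]
  gt[is.na(panel$dosage)] <- "./."
  lines <- paste(panel$chrom, panel$pos, panel$snp_ids, "A", "B", ".",
                 "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype panel
#'
#' Uses vcfR to parse the file and converts GT to alternate-allele
#' dosage. Only biallelic records are supported.
#'
#' @param path VCF path.
#' @param breed Named character vector mapping sample id to breed label;
#'   a single unnamed value is recycled.
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(path, breed = "A") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_panel requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  clean <- gsub("\\|", "/", t(gt))
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  samples <- rownames(dos)
  if (length(breed) == 1 && is.null(names(breed))) {
    br <- rep(breed, length(samples))
  } else {
    br <- unname(breed[samples])
    if (anyNA(br)) stop("breed labels missing for some samples")
  }
  genotype_panel(dos, br,
                 chrom = as.integer(vcfR::getCHROM(v)),
                 pos = as.integer(vcfR::getPOS(v)),
                 snp_ids = vcfR::getID(v))
}

#' Write / read a dosage TSV
#'
#' SNP rows with snp_id, chrom, pos metadata columns followed by one
#' column per sample (breed labels travel in the phenotype TSV).
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @return `path` (writer) or a plain list with dosage and metadata
#'   (reader; combine with breed labels via [genotype_panel()]).
#' @export
write_dosage_tsv <- function(panel, path) {
  df <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                   pos = panel$pos, t(panel$dosage),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param breed Breed labels (named by sample id or in column order).
#' @export
read_dosage_tsv <- function(path, breed = "A") {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- df[, c("snp_id", "chrom", "pos")]
  dos <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  colnames(dos) <- meta$snp_id
  samples <- rownames(dos)
  if (length(breed) == 1 && is.null(names(breed))) {
    br <- rep(breed, length(samples))
  } else if (!is.null(names(breed))) {
    br <- unname(breed[samples])
  } else {
    br <- breed
  }
  genotype_panel(dos, br, meta$chrom, meta$pos, sample_ids = samples,
                 snp_ids = meta$snp_id)
}

#' Write a gene map as 6-column BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start - 1` and `end` are written.
#'
#' @param genes Gene map data.frame.
#' @param path File path.
#' @export
write_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id, score = 0L,
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  gm <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                   start = bed$start + 1L, end = bed$end,
                   strand = bed$strand, stringsAsFactors = FALSE)
  gm <- gm[order(gm$chrom, gm$start), , drop = FALSE]
  rownames(gm) <- NULL
  class(gm) <- c("gene_map", "data.frame")
  gm
}

#' Write phenotypes as TSV
#'
#' @param traits A `trait_table`.
#' @param breed Per-sample breed labels.
#' @param path File path.
#' @export
write_phenotypes_tsv <- function(traits, breed, path) {
  df <- data.frame(sample_id = traits$sample_ids, breed = breed,
                   traits$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tn <- setdiff(colnames(df), c("sample_id", "breed"))
  vals <- as.matrix(df[, tn, drop = FALSE])
  rownames(vals) <- df$sample_id
  tt <- structure(
    list(sample_ids = df$sample_id,
         trait_names = tn,
         values = vals,
         trait_role = trait_roles()),
    class = "trait_table")
  list(traits = tt, breed = df$breed)
}

#' Write the simulation truth set
#'
#' Effects go to `<stem>.tsv` (causal SNP x trait); scalars and vectors
#' (ids, heritabilities, correlation targets, seed) to `<stem>.json`.
#'
#' @param truth A `truth_set`.
#' @param stem Path stem without extension.
#' @export
write_truth <- function(truth, stem) {
  eff <- data.frame(snp_id = rownames(truth$true_effects),
                    truth$true_effects, check.names = FALSE)
  utils::write.table(eff, paste0(stem, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(causal_snp_ids = truth$causal_snp_ids,
         true_h2 = as.list(truth$true_h2),
         true_genetic_corr = truth$true_genetic_corr,
         cm_threshold = truth$cm_threshold,
         seed = truth$seed),
    paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(stem)
}

#' Write a GRM as a square TSV with a header row of sample ids
#'
#' @param grm A [compute_grm()] result.
#' @param path File path.
#' @export
write_grm_tsv <- function(grm, path) {
  utils::write.table(grm$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write association results / generic tables as TSV
#'
#' @param df Data frame.
#' @param path File path.
#' @export
write_assoc_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an AWM as CSV plus a provenance sidecar TSV
#'
#' @param awm An `awm` object.
#' @param path CSV path for the z-score matrix (rows labelled by gene or
#'   SNP).
#' @param provenance_path Optional TSV path for the per-row provenance.
#' @export
write_awm_csv <- function(awm, path, provenance_path = NULL) {
  df <- data.frame(row_label = rownames(awm$z), awm$z,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, quote = TRUE, row.names = FALSE)
  if (!is.null(provenance_path)) {
    utils::write.table(awm$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a symmetric matrix (e.g. trait correlations) as TSV
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(name = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write PCIT edge lists and GraphML
#'
#' @param net A [pcit_filter()] result.
#' @param path Output path.
#' @param significant_only Restrict to significant edges.
#' @export
write_edges_tsv <- function(net, path, significant_only = FALSE) {
  e <- net$edges
  if (significant_only) e <- e[e$significant, , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net, significant_only = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
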