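# a 10-SNP x 12-trait toy association table with hand-set p-values and
# effects, plus a tiny gene map, reused across AWM step tests
make_toy_assoc <- function() {
  traits <- trait_names()
  snps <- paste0("s", 1:10)
  p <- matrix(0.9, 10, 12, dimnames = list(snps, traits))
  eff <- matrix(0, 10, 12, dimnames = list(snps, traits))
  withr::with_seed(42, eff[] <- rnorm(120))
  # key-trait (UDD) significance: s1..s6 and s9 in; s7, s8, s10 out
  p[c(1:6, 9), "UDD"] <- c(0.01, 0.04, 0.02, 0.049, 0.001, 0.03, 0.04)
  # s1: 5 other traits incl 2 udder -> secondary
  p["s1", c("FUA", "UB", "MY", "FAT", "PROT")] <- 0.01
  # s2: 5 other traits but only production -> primary only
  p["s2", c("MY", "FAT", "PROT", "FAT%", "PROT%")] <- 0.01
  # s3: 4 other traits (below the fixed threshold of 5)
  p["s3", c("FUA", "UC", "MY", "FAT")] <- 0.01
  # s4: 6 others incl 3 udder -> secondary
  p["s4", c("FUA", "UC", "UB", "MY", "FAT", "SCS")] <- 0.02
  # s5: nothing else
  # s6: 5 others incl 2 udder -> secondary
  p["s6", c("UC", "FTP", "MY", "CM", "SCS")] <- 0.03
  # s9: 2 others only
  p["s9", c("MY", "FAT")] <- 0.01
  # per-trait assoc_result list (chrom 1, positions 10kb apart)
  pos <- seq(10000L, by = 10000L, length.out = 10)
  assoc <- lapply(traits, function(tr) {
    structure(data.frame(snp_id = snps, chrom = 1L, pos = pos,
                         effect_allele = "B", maf = 0.2,
                         effect = eff[, tr], se = 0.1, p_raw = p[, tr],
                         p_bonferroni = pmin(1, p[, tr] * 10), n = 100L,
                         reason = NA_character_,
                         stringsAsFactors = FALSE),
              class = c("assoc_result", "data.frame"))
  })
  names(assoc) <- traits
  # genes: s1 and s2 both inside gene GA; s3 within 10 kb of GB;
  # s4 in GC; s5 exactly 10 kb from GC's end; s6, s9 far from genes
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC"),
    chrom = 1L,
    start = c(8000L, 24000L, 39000L),
    end = c(21000L, 26000L, 40000L),
    strand = "+", stringsAsFactors = FALSE)
  list(assoc = assoc, p = p, eff = eff, genes = genes, pos = pos)
}
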