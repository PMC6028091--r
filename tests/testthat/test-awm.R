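test_that("z-scoring uses the population-SD convention per trait", {
  eff <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
  z <- zscore_effects(eff)
  expect_equal(z[, "a"], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(apply(z, 2, popsd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_error(zscore_effects(cbind(c(1, 1, 1))), "constant")
})

test_that("primary selection thresholds raw key-trait p-values", {
  p <- matrix(c(0.01, 0.04, 0.06, 0.5, 0.049), 5, 1,
              dimnames = list(paste0("s", 1:5), "UDD"))
  expect_setequal(select_primary(p), c("s1", "s2", "s5"))
  p1 <- matrix(1, 5, 1, dimnames = dimnames(p))
  expect_length(select_primary(p1), 0)
  expect_error(select_primary(p, key_trait = "XX"), "unknown key trait")
})

test_that("null primary selection is binomial at rate alpha", {
  withr::with_seed(7, {
    p <- matrix(runif(10000 * 2), 10000, 2,
                dimnames = list(paste0("s", 1:10000), c("UDD", "MY")))
    sel <- select_primary(p)
    sigma <- sqrt(10000 * 0.05 * 0.95)
    expect_lt(abs(length(sel) - 500), 3 * sigma)
  })
})

test_that("dependency counting averages non-key associations", {
  toy <- make_toy_assoc()
  primary <- select_primary(toy$p)
  expect_setequal(primary, paste0("s", c(1:6, 9)))
  dep <- count_dependencies(primary, toy$p)
  # hand count of non-key p < 0.05: s1=5, s2=5, s3=4, s4=6, s5=0, s6=5, s9=2
  expect_equal(as.numeric(dep), mean(c(5, 5, 4, 6, 0, 5, 2)))
  per <- attr(dep, "per_snp")
  expect_equal(per[["s4"]], 6)
  expect_equal(per[["s5"]], 0)
  expect_error(count_dependencies(character(), toy$p), "no selected")
})

test_that("secondary selection enforces the udder-trait requirement", {
  toy <- make_toy_assoc()
  sec <- select_secondary(toy$p, min_other = 5, min_udder = 2)
  # s2 has 5 non-key production associations but no udder trait
  expect_false("s2" %in% sec)
  # s1: UDD + FUA + UB + MY + FAT + PROT = 5 others, 2 udder
  expect_true("s1" %in% sec)
  expect_setequal(as.character(sec), c("s1", "s4", "s6"))
  # brute force over the toy table
  primary <- select_primary(toy$p)
  other <- setdiff(trait_names(), "UDD")
  uo <- setdiff(udder_traits(), "UDD")
  manual <- primary[vapply(primary, function(s) {
    sum(toy$p[s, other] < 0.05) >= 5 && sum(toy$p[s, uo] < 0.05) >= 2
  }, logical(1))]
  expect_setequal(as.character(sec), manual)
  expect_true(all(sec %in% primary))
})

test_that("SNP-gene annotation handles containment, boundary, and gaps", {
  toy <- make_toy_assoc()
  ann <- annotate_snps(paste0("s", 1:10), rep(1L, 10), toy$pos,
                       toy$genes, window = 10000)
  expect_equal(ann$category[1], "in_gene")      # 10 kb inside GA
  expect_equal(ann$distance_bp[1], 0)
  expect_equal(ann$category[3], "within_10kb")  # 30 kb, 4 kb past GB end
  expect_equal(ann$nearest_gene_id[3], "GB")
  # s5 at 50 kb: exactly 10,000 bp past GC's end (40 kb) -> inclusive
  expect_equal(ann$distance_bp[5], 10000)
  expect_equal(ann$category[5], "within_10kb")
  # s6 at 60 kb: 20 kb past GC
  expect_equal(ann$category[6], "beyond_10kb")
  # chromosome without genes
  ann2 <- annotate_snps("x", 2L, 5000L, toy$genes)
  expect_equal(ann2$category, "beyond_10kb")
  expect_true(is.na(ann2$nearest_gene_id))
})

test_that("annotation matches the brute-force scan on random instances", {
  withr::with_seed(23, {
    genes <- simulate_gene_map(50, c(2e6, 2e6), mean_gene_length = 2e4,
                               seed = 24)
    chrom <- sample(1:2, 1000, replace = TRUE)
    pos <- floor(runif(1000, 1, 2e6))
    ann <- annotate_snps(paste0("s", 1:1000), chrom, pos, genes)
    ora <- oracle_annotate(chrom, pos, genes)
    expect_equal(ann$category, ora$category)
    expect_equal(ann$nearest_gene_id, ora$nearest_gene_id)
    expect_equal(ann$distance_bp, ora$distance_bp)
  })
})

test_that("per-gene deduplication ranks by trait count, then mean p, then position", {
  traits <- trait_names()
  p <- matrix(0.9, 3, 12, dimnames = list(c("a", "b", "c"), traits))
  # a: 6 associated traits, high mean p; b: 4 traits, tiny mean p
  p["a", 1:6] <- 0.04
  p["b", 1:4] <- 1e-6
  p["c", 1:6] <- 0.04   # same count as a, same p profile -> tie on pos
  ann <- data.frame(snp_id = c("a", "b", "c"),
                    category = "in_gene",
                    nearest_gene_id = "G1", distance_bp = 0,
                    stringsAsFactors = FALSE)
  pos <- c(a = 500, b = 100, c = 900)
  kept <- dedupe_per_gene(c("a", "b", "c"), ann, p, pos)
  expect_equal(kept, "a")   # count dominates p; position breaks the tie

  # single-SNP gene is kept; beyond_10kb SNP are never deduplicated
  ann2 <- data.frame(snp_id = c("a", "b"),
                     category = c("in_gene", "beyond_10kb"),
                     nearest_gene_id = c("G1", NA), distance_bp = c(0, 2e4),
                     stringsAsFactors = FALSE)
  expect_setequal(dedupe_per_gene(c("a", "b"), ann2, p[1:2, ], pos[1:2]),
                  c("a", "b"))
})

test_that("random dedupe instances match an exhaustive comparator", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 40
      ids <- paste0("s", 1:n)
      p <- matrix(runif(n * 12), n, 12,
                  dimnames = list(ids, trait_names()))
      gene <- sample(paste0("G", 1:8), n, replace = TRUE)
      cat_ <- sample(c("in_gene", "within_10kb", "beyond_10kb"), n,
                     replace = TRUE, prob = c(0.4, 0.3, 0.3))
      ann <- data.frame(snp_id = ids, category = cat_,
                        nearest_gene_id = ifelse(cat_ == "beyond_10kb",
                                                 NA, gene),
                        distance_bp = 0, stringsAsFactors = FALSE)
      pos <- setNames(sample(1e6, n), ids)
      kept <- dedupe_per_gene(ids, ann, p, pos)
      # comparator: full enumeration per gene
      expected <- ids[cat_ == "beyond_10kb"]
      for (g in unique(ann$nearest_gene_id[cat_ != "beyond_10kb"])) {
        members <- ids[cat_ != "beyond_10kb" & gene == g]
        nt <- rowSums(p[members, , drop = FALSE] < 0.05)
        mp <- rowMeans(p[members, , drop = FALSE])
        best <- members[order(-nt, mp, pos[members])][1]
        expected <- c(expected, best)
      }
      expect_setequal(kept, expected)
    }
  })
})

test_that("AWM assembly reproduces the hand-enumerated row set", {
  toy <- make_toy_assoc()
  awm <- build_awm(toy$assoc, toy$genes, min_other = 5)
  # candidates = primary {s1..s6, s9}; gene-assigned: s1,s2 (GA), s3 (GB),
  # s4 (GC), s5 (GC boundary); dedupe GA -> s1 (5+key assoc vs s2's 5+key;
  # s1 has 2 udder but count rule: s1 n_traits=6, s2 n_traits=6, tie ->
  # mean p decides), GC -> s4 (7 traits vs s5's 1)
  prov <- awm$provenance
  expect_setequal(prov$snp_id[prov$category != "beyond_10kb"],
                  c("s1", "s3", "s4"))
  expect_setequal(prov$snp_id[prov$category == "beyond_10kb"],
                  c("s6", "s9"))
  # set1/set2 partition identity
  expect_equal(awm$counts[["rows"]],
               awm$counts[["set1"]] + awm$counts[["set2"]])
  expect_equal(nrow(awm$z), 5)
  # row labels: genes for set1, snp ids for set2
  expect_setequal(rownames(awm$z), c("GA", "GB", "GC", "s6", "s9"))
  # provenance records the pleiotropy step
  expect_equal(sort(prov$snp_id[prov$selection_step == "secondary"]),
               c("s1", "s4", "s6"))
  # z-cells come from the full-panel z-scoring, all 12 traits present
  z_full <- zscore_effects(toy$eff)
  expect_equal(awm$z["GB", ], z_full["s3", ])
  expect_equal(ncol(awm$z), 12)
})

test_that("mean-p tie-break decides between equally pleiotropic gene SNP", {
  toy <- make_toy_assoc()
  # s1 and s2 both map GA with 6 associated traits each;
  # mean p: s1 has lower average (more small values) -> check directly
  mp1 <- mean(toy$p["s1", ])
  mp2 <- mean(toy$p["s2", ])
  awm <- build_awm(toy$assoc, toy$genes, min_other = 5)
  kept_ga <- awm$provenance$snp_id[awm$provenance$gene_id %in% "GA"]
  expect_equal(kept_ga, if (mp1 <= mp2) "s1" else "s2")
})

test_that("alpha = 1 admits every SNP and empty selections error", {
  toy <- make_toy_assoc()
  awm <- build_awm(toy$assoc, toy$genes, alpha = 1, min_other = 0,
                   min_udder = 0)
  expect_equal(awm$counts[["n_primary"]], 10)
  # all p > threshold -> explicit error with stage counts
  assoc_null <- lapply(toy$assoc, function(a) {
    a$p_raw <- 1
    a
  })
  expect_error(build_awm(assoc_null, toy$genes), "primary selection")
})

test_that("trait correlations from the AWM follow the Pearson formula", {
  withr::with_seed(55, {
    z <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("t1", "t2", "t3")))
    z <- cbind(z, t4 = z[, "t1"])
    R <- awm_trait_correlations(z)
    expect_equal(R["t1", "t4"], 1)
    # textbook formula by hand
    manual <- sum(scale(z[, 1]) * scale(z[, 2])) / (nrow(z) - 1)
    expect_equal(R["t1", "t2"], manual, tolerance = 1e-12)
    expect_equal(R, t(R))
    expect_equal(diag(R), setNames(rep(1, 4), colnames(z)))
  })
  expect_error(awm_trait_correlations(matrix(0, 2, 3)), "3 AWM rows")
  expect_error(awm_trait_correlations(cbind(a = c(1, 1, 1),
                                            b = c(1, 2, 3),
                                            c = c(2, 1, 3))),
               "constant")
})

test_that("breed overlap counts equal direct set algebra", {
  A <- paste0("s", 1:10)
  B <- paste0("s", 6:14)
  C <- paste0("s", c(1, 6, 7, 20))
  ov <- combine_breeds(list(A = A, B = B, C = C))
  expect_equal(ov$counts[["ABC"]], length(Reduce(intersect, list(A, B, C))))
  expect_equal(ov$counts[["only_A"]], length(setdiff(A, union(B, C))))
  expect_equal(ov$counts[["pair_AB"]], length(intersect(A, B)))
  expect_equal(ov$counts[["union"]], length(unique(c(A, B, C))))
  expect_setequal(ov$common_snp_ids, c("s6", "s7"))

  ident <- combine_breeds(list(A = A, B = A, C = A))
  expect_equal(ident$counts[["ABC"]], 10)
  disjoint <- combine_breeds(list(A = "x1", B = "x2", C = "x3"))
  expect_equal(unname(disjoint$counts[c("pair_AB", "pair_AC", "pair_BC",
                                        "ABC")]),
               c(0, 0, 0, 0))
})
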