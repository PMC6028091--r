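test_that("genotype simulation is seed-deterministic and self-consistent", {
  p1 <- simulate_genotypes(c(100, 100, 100), 1000,
                           maf_range = c(0.02, 0.5), seed = 1)
  p2 <- simulate_genotypes(c(100, 100, 100), 1000,
                           maf_range = c(0.02, 0.5), seed = 1)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$pos, p2$pos)
  p3 <- simulate_genotypes(c(100, 100, 100), 1000, seed = 2)
  expect_false(identical(p1$dosage, p3$dosage))

  expect_true(all(p1$dosage %in% 0:2))
  expect_lt(max(abs(p1$allele_freq - panel_allele_freq(p1))), 1e-12)
  for (ch in unique(p1$chrom)) {
    expect_true(all(diff(p1$pos[p1$chrom == ch]) > 0))
  }
})

test_that("degenerate frequency interval pins allele frequencies at 0.5", {
  p <- simulate_genotypes(c(10, 10, 10), 100, maf_range = c(0.5, 0.5),
                          fst = 0, seed = 3)
  # binomial sampling error for 10 cows: sd = sqrt(0.25 / 20) ~ 0.11
  expect_lt(max(abs(p$allele_freq - 0.5)), 0.11 * 4)
  expect_equal(mean(p$allele_freq), 0.5, tolerance = 0.02)
})

test_that("sampled frequency spectrum is uniform over the MAF range", {
  p <- simulate_genotypes(c(10, 10, 10), 40000, maf_range = c(0.02, 0.5),
                          seed = 1)
  f <- attr(p, "ancestral_freq")
  breaks <- seq(0.02, 0.5, length.out = 21)
  counts <- hist(f, breaks = breaks, plot = FALSE)$counts
  expected <- 40000 / 20
  sigma <- sqrt(40000 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_genotypes(c(0, 10, 10), 100), "positive")
  expect_error(simulate_genotypes(c(10, 10), 100, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(simulate_genotypes(c(10, 10), 100, maf_range = c(0.1, 0.6)),
               "maf_range")
  expect_error(simulate_genotypes(c(10, 10), 2, n_chrom = 5), "per chrom")
})

test_that("gene maps are valid, sorted and seed-deterministic", {
  expect_equal(nrow(simulate_gene_map(0, c(1e6))), 0)

  g1 <- simulate_gene_map(1, 1e6, mean_gene_length = 1e4, seed = 7)
  expect_equal(nrow(g1), 1)
  expect_gte(g1$start, 1)
  expect_lte(g1$end, 1e6)
  expect_lte(g1$start, g1$end)

  gm <- simulate_gene_map(200, c(5e6, 5e6, 4e6), seed = 11)
  expect_equal(nrow(gm), 200)
  expect_false(any(duplicated(gm$gene_id)))
  for (ch in unique(gm$chrom)) {
    g <- gm[gm$chrom == ch, ]
    expect_true(all(diff(g$start) > 0))
    expect_true(all(g$start[-1] > g$end[-nrow(g)])) # non-overlapping
  }
  expect_identical(gm, simulate_gene_map(200, c(5e6, 5e6, 4e6), seed = 11))
  expect_error(simulate_gene_map(1000, 1e6, mean_gene_length = 1e4),
               "infeasible")
})

test_that("uniform SNP hit the padded-gene union at its closed-form rate", {
  lens <- c(8e6, 8e6)
  gm <- simulate_gene_map(150, lens, mean_gene_length = 2e4, seed = 5)
  frac <- gene_coverage_fraction(gm, lens, window = 10000)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.9)
  withr::with_seed(99, {
    chrom <- sample(1:2, 10000, replace = TRUE)
    pos <- floor(runif(10000, 1, lens[1])) # equal lengths
    ann <- annotate_snps(paste0("s", 1:10000), chrom, pos, gm,
                         window = 10000)
    hit <- mean(ann$category != "beyond_10kb")
    sigma <- sqrt(frac * (1 - frac) / 10000)
    expect_lt(abs(hit - frac), 3 * sigma + 1e-9)
  })
})

test_that("phenotype simulation recovers target heritabilities", {
  p <- simulate_genotypes(c(1000, 1000, 1000), 400, seed = 21)
  sim <- simulate_phenotypes(p, n_causal = 200,
                             target_h2 = rep(0.99, 12), seed = 22)
  h2 <- realized_h2(sim$traits, sim$truth)
  expect_true(all(abs(h2 - 0.99) < 0.03))

  # moderate targets, canonical defaults
  sim2 <- simulate_phenotypes(p, n_causal = 200, seed = 23)
  h2b <- realized_h2(sim2$traits, sim2$truth)
  expect_true(all(abs(h2b - default_h2()) < 0.06))
  expect_true(all(sim2$traits$values[, "CM"] %in% c(0, 1)))
  expect_equal(mean(sim2$traits$values[, "CM"]), 0.25, tolerance = 0.02)
})

test_that("independent effect draws leave genetic values uncorrelated", {
  p <- simulate_genotypes(c(700, 700, 700), 600, seed = 31)
  sim <- simulate_phenotypes(p, n_causal = 300, target_corr = diag(12),
                             target_h2 = rep(0.5, 12), seed = 32)
  R <- realized_genetic_corr(sim$truth)
  off <- R[upper.tri(R)]
  expect_lt(max(abs(off)), 3 / sqrt(300))
})

test_that("planted FUA-UB genetic correlation of 0.40 is realized", {
  p <- simulate_genotypes(c(700, 700, 600), 800, seed = 41)
  sim <- simulate_phenotypes(p, n_causal = 500, seed = 42)
  R <- realized_genetic_corr(sim$truth)
  expect_lt(abs(R["FUA", "UB"] - 0.40), 0.1)
})

test_that("phenotype simulation validates its inputs", {
  p <- simulate_genotypes(c(10, 10, 10), 50, seed = 51)
  expect_error(simulate_phenotypes(p, n_causal = 51), "n_causal")
  bad <- diag(12); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(simulate_phenotypes(p, 10, target_corr = bad),
               "positive semi-definite")
  expect_error(simulate_phenotypes(p, 10, target_h2 = rep(1.2, 12)),
               "target_h2")
})

test_that("somatic cell score transform matches its definition and inverts", {
  expect_identical(scs_from_scc(100000), 3)
  expect_identical(scs_from_scc(200000), 4)
  expect_identical(scs_from_scc(50000), 2)
  expect_error(scs_from_scc(0), "positive")
  scc <- c(1e3, 5e4, 1e5, 3.7e5, 9e6)
  expect_equal(scc_from_scs(scs_from_scc(scc)), scc, tolerance = 1e-12)
  expect_true(all(diff(scs_from_scc(sort(scc))) > 0))
})

test_that("yield-deviation heritability follows the record-averaged formula", {
  expect_equal(yd_heritability(0.3, 0.5, 2.5), 0.6)
  expect_equal(yd_heritability(0.4, 0.4, 1), 0.5)
  n <- c(1, 2, 5, 20, 1e6)
  h <- yd_heritability(0.3, 0.5, n)
  expect_true(all(diff(h) > 0))
  expect_equal(h[5], 1.0, tolerance = 1e-5)
  expect_error(yd_heritability(-0.1, 0.5, 2), "positive")
  expect_error(yd_heritability(0.3, 0.5, 0.5), "n_records")
})

test_that("indefinite correlation tables are repaired minimally", {
  R <- default_genetic_corr()
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(diag(R), setNames(rep(1, 12), trait_names()))
  expect_equal(R["FUA", "UB"], 0.40, tolerance = 0.02)
  # already-PSD input passes through unchanged
  I12 <- diag(12)
  expect_equal(nearest_correlation(I12), I12)
})
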