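# Independent reference implementations used as correctness oracles.
# These deliberately use the slowest, most literal formulation of each
# computation and share no code with the package internals.

# GRM: element-by-element triple loop over the printed formula
oracle_grm <- function(X) {
  n <- nrow(X)
  W <- ncol(X)
  p <- colMeans(X) / 2
  G <- matrix(0, n, n)
  for (j in 1:n) {
    for (k in 1:n) {
      acc <- 0
      for (i in 1:W) {
        acc <- acc + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
      }
      G[j, k] <- acc / W
    }
  }
  G
}

# PCIT: naive enumeration of all trios under the documented clamp and
# degenerate-term rules; returns the logical keep matrix.
oracle_pcit_keep <- function(C) {
  n <- nrow(C)
  clamp <- 1 - 1e-9
  ztol <- 1e-12
  Cc <- pmin(pmax(C, -clamp), clamp)
  keep <- matrix(TRUE, n, n)
  if (n < 3) return(keep)
  for (x in 1:(n - 1)) {
    for (y in (x + 1):n) {
      for (z in 1:n) {
        if (z == x || z == y) next
        r1 <- Cc[x, y]; r2 <- Cc[x, z]; r3 <- Cc[y, z]
        p1 <- (r1 - r2 * r3) / sqrt((1 - r2^2) * (1 - r3^2))
        p2 <- (r2 - r1 * r3) / sqrt((1 - r1^2) * (1 - r3^2))
        p3 <- (r3 - r1 * r2) / sqrt((1 - r1^2) * (1 - r2^2))
        v1 <- abs(r1) >= ztol
        v2 <- abs(r2) >= ztol
        v3 <- abs(r3) >= ztol
        t1 <- if (v1) p1 / r1 else 0
        t2 <- if (v2) p2 / r2 else 0
        t3 <- if (v3) p3 / r3 else 0
        nv <- v1 + v2 + v3
        if (nv == 0) next
        eps <- (t1 + t2 + t3) / nv
        if (abs(r1) < abs(eps * r2) && abs(r1) < abs(eps * r3)) {
          keep[x, y] <- keep[y, x] <- FALSE
        }
      }
    }
  }
  keep
}

# SNP-gene annotation: O(n * m) scan with the lower-start tie-break
oracle_annotate <- function(chrom, pos, genes, window = 10000) {
  n <- length(pos)
  out <- data.frame(category = rep("beyond_10kb", n),
                    nearest_gene_id = NA_character_,
                    distance_bp = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    d <- pmax(0, pmax(g$start - pos[i], pos[i] - g$end))
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(g$start[best])]
    out$nearest_gene_id[i] <- g$gene_id[best]
    out$distance_bp[i] <- d[best]
    out$category[i] <- if (d[best] == 0) "in_gene"
      else if (d[best] <= window) "within_10kb" else "beyond_10kb"
  }
  out
}

# connected components by union-find on a significant edge list
oracle_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) {
    while (parent[[a]] != a) a <- parent[[a]]
    a
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$node_a[i]); rb <- find(edges$node_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# random correlation-like matrix from a small data sample
random_corr <- function(n_nodes, n_vars = 12) {
  M <- matrix(stats::rnorm(n_nodes * n_vars), n_nodes)
  C <- stats::cor(t(M))
  (C + t(C)) / 2
}

# deterministic dosage vector with allele frequency ~f (as heterozygotes)
rbinom_fixed <- function(n, f) {
  k <- round(2 * n * f)
  out <- integer(n)
  h <- min(k, n)
  out[seq_len(h)] <- 1L
  if (k > n) out[seq_len(k - n)] <- 2L
  out
}

# hand-built panel with exact dosage control: `dosage` is samples x SNP
toy_panel <- function(dosage, breed = rep("A", nrow(dosage)),
                      chrom = rep(1L, ncol(dosage)),
                      pos = seq_len(ncol(dosage)) * 1000L) {
  genotype_panel(as.matrix(dosage), breed, chrom, pos)
}
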