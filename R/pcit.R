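#' Row-wise co-association correlations
#'
#' Pearson correlation between every pair of AWM rows across the trait
#' columns: two SNP/genes with similar multi-trait effect profiles get a
#' high correlation, the raw material for PCIT edge filtering. Constant
#' rows are dropped with a warning (their correlation is undefined).
#'
#' @param awm An `awm` object or a rows x traits numeric matrix with at
#'   least 3 columns.
#' @return Symmetric node x node correlation matrix (unit diagonal).
#' @export
row_correlations <- function(awm) {
  z <- if (inherits(awm, "awm")) awm$z else awm
  if (ncol(z) < 3) stop("need at least 3 trait columns")
  sds <- apply(z, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant AWM rows")
    z <- z[sds > 0, , drop = FALSE]
  }
  R <- stats::cor(t(z))
  (R + t(R)) / 2
}

#' PCIT: partial-correlation with information-theory edge filtering
#'
#' For every trio of nodes (x, y, z) the three first-order partial
#' correlations are computed, e.g.
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' and the local tolerance is the average shrinkage
#' `eps_xyz = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3`.
#' The x-y association is flagged non-significant if some third node z
#' explains it: `|r_xy| < |eps * r_xz|` and `|r_xy| < |eps * r_yz|`.
#' Edges surviving every trio are significant.
#'
#' Numerical guards: correlations are clamped to `1 - 1e-9` in magnitude
#' before any partial correlation is formed; a ratio term whose direct
#' correlation is below 1e-12 in magnitude is skipped and the tolerance
#' averages the remaining terms; a trio with all three terms degenerate
#' is skipped entirely (it can reject nothing). Edges with r exactly 0
#' are recorded but can never be significant. With fewer than three
#' nodes no trio exists and every nonzero edge survives vacuously.
#'
#' @param corr Symmetric node x node correlation matrix with unit
#'   diagonal (e.g. [row_correlations()] output).
#' @param max_nodes Refuse above this node count unless `force = TRUE`
#'   (trio enumeration is cubic; default 3000).
#' @param force Override the node-count ceiling.
#' @return An object of class `pcit_network`: `nodes` (labels), `edges`
#'   (data.frame node_a, node_b, r, significant for every unordered
#'   pair), and `n_significant`.
#' @export
pcit_filter <- function(corr, max_nodes = 3000, force = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  n <- nrow(corr)
  if (n > max_nodes && !force) {
    stop("correlation matrix has ", n, " nodes (> max_nodes = ",
         max_nodes, "); trio enumeration is O(n^3), use force = TRUE ",
         "to run anyway")
  }
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  if (max(abs(corr)) > 1 + 1e-8) stop("entries must be in [-1, 1]")
  labels <- rownames(corr)
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  clamp <- 1 - 1e-9
  zero_tol <- 1e-12
  Cc <- pmin(pmax(corr, -clamp), clamp)
  keep <- matrix(TRUE, n, n)
  if (n >= 3) {
    D <- 1 - Cc^2
    absC <- abs(Cc)
    V1 <- absC >= zero_tol
    for (z in seq_len(n)) {
      cz <- Cc[, z]
      dz <- 1 - cz^2
      czx <- matrix(cz, n, n)              # cz by row index (x)
      czy <- matrix(cz, n, n, byrow = TRUE)  # cz by column index (y)
      P1 <- (Cc - tcrossprod(cz)) / sqrt(tcrossprod(dz))
      P2 <- (czx - Cc * czy) / sqrt(D * matrix(dz, n, n, byrow = TRUE))
      P3 <- (czy - Cc * czx) / sqrt(D * matrix(dz, n, n))
      V2 <- abs(czx) >= zero_tol
      V3 <- abs(czy) >= zero_tol
      T1 <- ifelse(V1, P1 / Cc, 0)
      T2 <- ifelse(V2, P2 / czx, 0)
      T3 <- ifelse(V3, P3 / czy, 0)
      nv <- V1 + V2 + V3
      eps <- (T1 + T2 + T3) / pmax(nv, 1L)
      rej <- nv > 0 & absC < abs(eps * czx) & absC < abs(eps * czy)
      rej[z, ] <- FALSE
      rej[, z] <- FALSE
      diag(rej) <- FALSE
      keep <- keep & !rej
    }
  }
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  edges <- data.frame(
    node_a = labels[ut[, 1]], node_b = labels[ut[, 2]],
    r = r,
    significant = keep[ut] & r != 0,
    stringsAsFactors = FALSE)
  structure(list(nodes = labels, edges = edges,
                 n_significant = sum(edges$significant)),
            class = "pcit_network")
}

#' @export
print.pcit_network <- function(x, ...) {
  cat("pcit_network:", length(x$nodes), "nodes;",
      x$n_significant, "of", nrow(x$edges), "edges significant\n")
  invisible(x)
}

#' Convert the significant subgraph to an igraph object
#'
#' @param net A [pcit_filter()] result.
#' @param significant_only Keep only significant edges (default TRUE).
#' @return An undirected igraph graph with edge attribute `r`; isolated
#'   nodes are retained as vertices.
#' @export
as_igraph <- function(net, significant_only = TRUE) {
  e <- net$edges
  if (significant_only) e <- e[e$significant, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("node_a", "node_b", "r")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
}

#' Summary statistics of a PCIT network
#'
#' Node count, significant-edge count, degree distribution and connected
#' components of the significant subgraph.
#'
#' @param net A [pcit_filter()] result.
#' @return List with `n_nodes`, `n_edges_significant`, `degree` (named
#'   per-node degrees in the significant subgraph), `degree_table`
#'   (tabulated distribution) and `components` (list: count, sizes).
#' @export
network_summary <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  nontrivial <- comp$csize[comp$csize > 1]
  list(
    n_nodes = length(net$nodes),
    n_edges_significant = net$n_significant,
    degree = deg,
    degree_table = table(deg),
    components = list(count = comp$no,
                      count_nontrivial = length(nontrivial),
                      sizes = sort(as.integer(comp$csize),
                                   decreasing = TRUE)))
}
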