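#' REML fit of the null polygenic model
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, sigma_u^2 G)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood, using a
#' one-time eigendecomposition of `G` and a bounded scalar search over
#' `log(lambda)` with `lambda = sigma_u^2 / sigma_e^2` (EMMA-style
#' profiling: for fixed lambda the mean and the residual scale have
#' closed-form REML solutions).
#'
#' @param grm A [compute_grm()] result (or `grm`-classed list).
#' @param y Numeric trait vector, same length/order as the GRM samples.
#' @param bounds Search bounds on `log(lambda)` (default `c(-10, 10)`).
#' @param tol Convergence tolerance of the scalar search (default 1e-8).
#' @param trait,breed Optional labels carried into the fit.
#' @param eig Optional precomputed `eigen(G, symmetric = TRUE)` result,
#'   shared across traits on the same cohort to avoid repeating the
#'   decomposition.
#' @return An object of class `mlm_fit` with `mu`, `var_u`, `var_e`,
#'   `lambda`, `h2`, `loglik_reml`, `n` and the eigendecomposition
#'   (`eig$values`, `eig$vectors`) of `G` for reuse in [mlma_scan()].
#' @export
fit_null_model <- function(grm, y, bounds = c(-10, 10), tol = 1e-8,
                           trait = NA_character_, breed = NA_character_,
                           eig = NULL) {
  G <- grm$matrix
  n <- nrow(G)
  if (length(y) != n) stop("length(y) must equal the GRM dimension")
  if (anyNA(y)) stop("y must be complete")
  if (is.null(eig)) eig <- eigen(G, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop("G is not positive semi-definite (min eigenvalue ",
         signif(min(eig$values), 3), ")")
  }
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  xt <- crossprod(U, rep(1, n))

  reml_ll <- function(loglam) {
    lam <- exp(loglam)
    v <- lam * d + 1
    w <- 1 / v
    xwx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / xwx
    r <- yt - xt * mu
    rss <- sum(w * r^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(v)) + log(xwx))
  }
  opt <- stats::optimize(reml_ll, interval = bounds, maximum = TRUE,
                         tol = tol)
  # compare against the boundaries: optimize() can miss a boundary optimum
  cand <- c(opt$maximum, bounds)
  ll <- c(opt$objective, reml_ll(bounds[1]), reml_ll(bounds[2]))
  loglam <- cand[which.max(ll)]
  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  xwx <- sum(w * xt^2)
  mu <- sum(w * xt * yt) / xwx
  rss <- sum(w * (yt - xt * mu)^2)
  var_e <- rss / (n - 1)
  var_u <- lam * var_e
  structure(
    list(trait = trait, breed = breed, mu = mu,
         var_u = var_u, var_e = var_e, lambda = lam,
         h2 = var_u / (var_u + var_e),
         loglik_reml = max(ll), n = n,
         eig = list(values = d, vectors = U),
         yt = as.numeric(yt), xt = as.numeric(xt)),
    class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("mlm_fit: n =", x$n,
      " var_u =", signif(x$var_u, 4),
      " var_e =", signif(x$var_e, 4),
      " h2 =", round(x$h2, 3), "\n")
  invisible(x)
}

#' Single-SNP mixed-linear-model association scan
#'
#' For each SNP, the allele-substitution effect is estimated by
#' generalized least squares under `V = sigma_u^2 G + sigma_e^2 I`, with
#' the variance ratio fixed at the null-model REML fit (the candidate SNP
#' stays in `G`; no leave-one-chromosome-out). The overall variance scale
#' is re-estimated per SNP from the GLS residual sum of squares and the
#' Wald test uses a t reference with `n - 2` degrees of freedom, so with
#' `G = I` the scan collapses exactly to the ordinary least-squares
#' t-test. Bonferroni p-values multiply by the number of tested
#' (non-constant) SNP.
#'
#' @param panel A QC-passed [genotype_panel()] for the fitted cohort.
#' @param y Trait vector used in `fit` (same order as panel samples).
#' @param fit A [fit_null_model()] result on the same cohort.
#' @param Xt Optional precomputed `crossprod(U, panel$dosage)` with `U`
#'   the eigenvectors in `fit`; shared across traits on the same panel.
#' @return An `assoc_result` data.frame: snp_id, chrom, pos,
#'   effect_allele, maf, effect, se, p_raw, p_bonferroni, n, reason
#'   (NA, or "constant" for untestable SNP whose effect is missing).
#' @export
mlma_scan <- function(panel, y, fit, Xt = NULL) {
  n <- fit$n
  if (length(panel$sample_ids) != n) {
    stop("panel and fit refer to different cohorts")
  }
  U <- fit$eig$vectors
  d <- fit$eig$values
  w <- 1 / (fit$lambda * d + 1)
  yt <- fit$yt
  xt <- fit$xt
  if (is.null(Xt)) Xt <- crossprod(U, panel$dosage)  # n x m
  wy <- w * yt
  wx0 <- w * xt
  s_yy <- sum(wy * yt)
  a11 <- sum(wx0 * xt)
  b1 <- sum(wx0 * yt)
  a12 <- as.numeric(crossprod(Xt, wx0))
  a22 <- as.numeric(crossprod(Xt^2, w))
  b2 <- as.numeric(crossprod(Xt, wy))
  det <- a11 * a22 - a12^2
  sds <- apply(panel$dosage, 2, stats::sd)
  constant <- sds == 0 | det <= 1e-12 * pmax(a11 * a22, 1)
  beta <- (a11 * b2 - a12 * b1) / det
  rss <- pmax(s_yy - (a22 * b1^2 - 2 * a12 * b1 * b2 + a11 * b2^2) / det, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * a11 / det)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  beta[constant] <- NA_real_
  se[constant] <- NA_real_
  p[constant] <- NA_real_
  m <- sum(!constant)
  p_bonf <- pmin(1, p * m)
  af <- colMeans(panel$dosage) / 2
  out <- data.frame(
    snp_id = panel$snp_ids, chrom = panel$chrom, pos = panel$pos,
    effect_allele = "B", maf = pmin(af, 1 - af),
    effect = beta, se = se, p_raw = p, p_bonferroni = p_bonf,
    n = n,
    reason = ifelse(constant, "constant", NA_character_),
    stringsAsFactors = FALSE)
  attr(out, "m_tests") <- m
  attr(out, "trait") <- fit$trait
  attr(out, "breed") <- fit$breed
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' GWAS for one breed across all traits
#'
#' Convenience wrapper used by the pipeline: computes the cohort GRM,
#' fits the null model per trait and runs [mlma_scan()] for each trait
#' column of the trait table.
#'
#' @param panel Single-breed QC-passed [genotype_panel()].
#' @param traits A `trait_table` covering (at least) the panel samples.
#' @param breed Label recorded in the results.
#' @param on_monomorphic Passed to [compute_grm()].
#' @param grm Optional precomputed [compute_grm()] result for the panel.
#' @return Named list of `assoc_result` data.frames, one per trait.
#' @export
gwas_scan_traits <- function(panel, traits, breed = NA_character_,
                             on_monomorphic = "drop", grm = NULL) {
  idx <- match(panel$sample_ids, traits$sample_ids)
  if (anyNA(idx)) stop("panel samples missing from trait table")
  if (is.null(grm)) grm <- compute_grm(panel, on_monomorphic = on_monomorphic)
  Y <- traits$values[idx, , drop = FALSE]
  eig <- eigen(grm$matrix, symmetric = TRUE)
  Xt <- crossprod(eig$vectors, panel$dosage)
  out <- lapply(colnames(Y), function(tr) {
    fit <- fit_null_model(grm, Y[, tr], trait = tr, breed = breed,
                          eig = eig)
    mlma_scan(panel, Y[, tr], fit, Xt = Xt)
  })
  names(out) <- colnames(Y)
  out
}
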