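#' Trait panel used throughout the package
#'
#' The analysis operates on twelve dairy-cow yield-deviation traits: five
#' udder conformation traits (fore udder attachment FUA, udder
#' depth/development UDD, udder cleft UC, udder balance UB, front teat
#' placement FTP), five production traits (milk yield MY, fat and protein
#' yields FAT/PROT and contents FAT%/PROT%) and two udder-health traits
#' (clinical mastitis CM, coded 0/1, and somatic cell score SCS).
#'
#' @return Character vector of the 12 trait names, in canonical order.
#' @export
trait_names <- function() {
  c("FUA", "UDD", "UC", "UB", "FTP",
    "MY", "FAT", "PROT", "FAT%", "PROT%",
    "CM", "SCS")
}

#' Trait roles
#'
#' Each trait carries a role used by the AWM selection rules: the key trait
#' anchoring primary SNP selection (UDD by default), the remaining udder
#' conformation traits, the production traits, and the health traits.
#' `udder_traits()` returns the five conformation traits; the key trait is
#' itself an udder trait, so the pleiotropy rule "at least two udder traits
#' among the non-key associations" is evaluated against
#' `setdiff(udder_traits(), key_trait)`.
#'
#' @param key_trait Name of the key trait (default `"UDD"`).
#' @return `trait_roles()`: named character vector mapping trait to role in
#'   `{key, udder, production, health}`. `udder_traits()`: the five udder
#'   conformation trait names.
#' @export
trait_roles <- function(key_trait = "UDD") {
  tr <- trait_names()
  if (!key_trait %in% tr) {
    stop("unknown key trait: ", key_trait)
  }
  roles <- c(
    FUA = "udder", UDD = "udder", UC = "udder", UB = "udder", FTP = "udder",
    MY = "production", FAT = "production", PROT = "production",
    `FAT%` = "production", `PROT%` = "production",
    CM = "health", SCS = "health"
  )
  roles[key_trait] <- "key"
  roles[tr]
}

#' @rdname trait_roles
#' @export
udder_traits <- function() {
  c("FUA", "UDD", "UC", "UB", "FTP")
}

#' Default genetic parameter targets for the simulator
#'
#' A 12-trait heritability vector and genetic correlation matrix with the
#' structure typical of French dairy cattle yield deviations: moderate
#' heritabilities for conformation traits, high for production contents,
#' very low for clinical mastitis; strong MY-FAT-PROT correlations,
#' moderate positive correlations among udder conformation traits, and low
#' correlations elsewhere (e.g. FUA-UB = 0.40). Published correlation
#' tables of this kind are estimated entry-by-entry and are often slightly
#' indefinite; `default_genetic_corr()` therefore passes the raw table
#' through [nearest_correlation()] before returning it.
#'
#' @return `default_genetic_corr()`: a 12 x 12 positive semi-definite
#'   correlation matrix; `default_h2()`: named per-trait heritabilities.
#' @export
default_genetic_corr <- function() {
  tr <- trait_names()
  R <- diag(12)
  dimnames(R) <- list(tr, tr)
  up <- list(
    FUA = c(UDD = -0.11, FTP = -0.28, UB = 0.40, UC = 0.37, MY = 0.42,
            FAT = 0.43, PROT = 0.39, `FAT%` = 0.03, `PROT%` = -0.05,
            CM = 0.19, SCS = -0.05),
    UDD = c(FTP = -0.39, UB = -0.38, UC = 0.37, MY = 0.33, FAT = 0.32,
            PROT = 0.31, `FAT%` = -0.02, `PROT%` = -0.08, CM = 0.09,
            SCS = 0.03),
    FTP = c(UB = -0.24, UC = -0.15, MY = 0.20, FAT = 0.22, PROT = 0.21,
            `FAT%` = 0.06, `PROT%` = 0.04, CM = 0.06, SCS = 0.02),
    UB = c(UC = -0.03, MY = 0.02, FAT = 0.01, PROT = 0.00, `FAT%` = 0.00,
           `PROT%` = -0.03, CM = -0.09, SCS = -0.02),
    UC = c(MY = -0.01, FAT = -0.01, PROT = -0.01, `FAT%` = -0.05,
           `PROT%` = -0.06, CM = 0.00, SCS = -0.05),
    MY = c(FAT = 0.88, PROT = 0.94, `FAT%` = -0.22, `PROT%` = -0.13,
           CM = 0.02, SCS = 0.02),
    FAT = c(PROT = 0.90, `FAT%` = 0.26, `PROT%` = 0.09, CM = -0.01,
            SCS = 0.02),
    PROT = c(`FAT%` = -0.06, `PROT%` = 0.20, CM = 0.01, SCS = 0.05),
    `FAT%` = c(`PROT%` = 0.46, CM = -0.03, SCS = -0.02),
    `PROT%` = c(CM = -0.03, SCS = 0.00),
    CM = c(SCS = 0.20)
  )
  for (a in names(up)) {
    for (b in names(up[[a]])) {
      R[a, b] <- up[[a]][[b]]
      R[b, a] <- up[[a]][[b]]
    }
  }
  nearest_correlation(R)
}

#' @rdname default_genetic_corr
#' @export
default_h2 <- function() {
  c(FUA = 0.34, UDD = 0.37, UC = 0.30, UB = 0.36, FTP = 0.43,
    MY = 0.50, FAT = 0.44, PROT = 0.44, `FAT%` = 0.68, `PROT%` = 0.66,
    CM = 0.03, SCS = 0.39)
}

#' Repair an indefinite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `eps` are raised to `eps`, the
#' matrix is reconstructed and rescaled to unit diagonal. Identity on
#' matrices that are already positive semi-definite (up to symmetrisation).
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eps Smallest admissible eigenvalue (default 1e-8).
#' @return A positive semi-definite correlation matrix with the same
#'   dimnames.
#' @export
nearest_correlation <- function(R, eps = 1e-8) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) {
    return(R)
  }
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}
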