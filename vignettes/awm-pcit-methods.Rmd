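---
title: "Methods: multi-breed AWM construction and PCIT network filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-breed AWM construction and PCIT network filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(awmpcit)
```

This vignette documents the statistical model behind `awmpcit`, the
assumptions it makes, the defaults it chooses and why, and the numerical
and design decisions a maintainer should know about. It states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis in one paragraph

Three dairy-cattle breed cohorts are analysed within breed: marker QC,
then a single-SNP mixed-linear-model scan for each of 12 yield-deviation
traits (five udder conformation traits FUA, UDD, UC, UB, FTP; five
production traits MY, FAT, PROT, FAT%, PROT%; and SCS and CM). The
Association Weight Matrix (AWM) selects pleiotropic SNP anchored on the
key trait (UDD), collapses gene-proximal SNP to one representative per
gene, and stores z-scored allele-substitution effects for all 12 traits.
Column correlations of this matrix estimate trait co-association
("SNP-based correlations"); row correlations feed the PCIT filter, which
discards SNP/gene edges explainable through a third variable. The
three per-breed AWMs are intersected to a common SNP/gene set.

## 2. Mixed-model association

For trait *y* (a yield deviation: a phenotype pre-adjusted for
non-genetic effects and, for repeated records, permanent environment)
the null model is

$$y = 1\mu + u + e,\qquad u \sim N(0, G\sigma^2_u),\quad
  e \sim N(0, I\sigma^2_e),$$

with $G$ the genomic relationship matrix
$g_{jk} = W^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$
computed from observed within-cohort allele frequencies over the $W$
QC-passed markers. Yield deviations average $n$ records, which divides
the residual variance: `yd_heritability(va, vr, n) = va / (va + vr/n)`
— the reason these pseudo-phenotypes have high heritability and good
detection power.

Estimation follows the EMMA profiling idea: one symmetric
eigendecomposition of $G$, then a bounded scalar REML search over
$\log\lambda$, $\lambda=\sigma^2_u/\sigma^2_e$, on $[-10, 10]$ with
tolerance $10^{-8}$. For fixed $\lambda$, the mean and residual scale
have closed forms, so the search is one-dimensional and monotone-safe;
the boundary values are checked explicitly because a golden-section
search can miss a boundary optimum (relevant when the true
$\sigma^2_u$ is 0).

The per-SNP scan fixes the variance *ratio* at the null fit
(EMMAX/GCTA-MLMA convention; a per-SNP refit option was considered and
rejected as 10–100× the cost for negligible change at these effect
sizes) but re-estimates the overall scale from the GLS residual sum of
squares of the two-parameter model, testing with a $t_{n-2}$ reference.
Two consequences we consider features: with $G=I$ the scan collapses
*exactly* to the OLS t-test, and the null distribution is calibrated in
small samples. The candidate SNP remains in $G$ (no
leave-one-chromosome-out), matching the "all autosomes" construction;
proximal contamination is a known, accepted bias of this choice.
Bonferroni correction multiplies by the number of tested (non-constant)
SNP.

QC retains a SNP when call rate > 0.99, MAF > 0.02 in *at least one*
breed (a deliberately permissive rule: a SNP informative in one breed is
kept for all, and within-breed monomorphic markers are dropped from that
breed's GRM with a log message), and no Hardy–Weinberg departure at
$p < 10^{-4}$. HWE is tested *within breed*: pooling diverged cohorts
would produce a Wahlund heterozygote deficit and reject well-genotyped
markers. The reported `hwe_p` is the minimum across breeds.

## 3. AWM construction

Step thresholds are configuration keys with these defaults:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | raw p-value threshold for steps 1–3 |
| `min_other` | data-driven | rounded mean dependency count from step 2 |
| `min_udder` | 2 | non-key udder traits required in step 3 |
| `window_bp` | 10,000 | SNP-to-gene proximity window (inclusive) |
| `bonferroni_alpha` | 0.05 | threshold for the GWAS summary tables only |

Two points were genuinely open and are worth recording:

* **Raw versus genome-wide p in step 1.** The AWM methodology selects at
  a nominal p < 0.05 to admit moderate pleiotropic signals; the
  Bonferroni threshold is reserved for the single-trait summary tables.
  Both are config keys, so a conservative user can anchor step 1 on
  `p_bonferroni` instead.
* **Scope of step 3.** We filter the *primary* set for pleiotropy, so
  the selected rows always satisfy `secondary ⊆ primary`, and rows
  passing the filter are labelled `selection_step = "secondary"` in the
  provenance. The original AWM literature also describes a rescue
  variant in which step 3 scans all SNP and can add rows never
  associated with the key trait; this is available as
  `secondary_from_all = TRUE` but is off by default because the key
  trait should anchor the matrix.

Annotation distance is the base-pair gap between the SNP position and
the nearest gene interval edge on the same chromosome (0 inside a gene),
with the 10-kb boundary inclusive and equidistant ties resolved toward
the lower-start gene. Deduplication keeps, per gene, the SNP associated
with the most traits (p < `alpha` over all 12), breaking ties by lowest
mean raw p across all 12 traits and then by smallest position —
deterministic by construction. Intergenic (`beyond_10kb`) SNP are never
deduplicated (they have no gene key) and enter the matrix as set2 rows
labelled by SNP id; the final rows partition exactly into set1
(gene-labelled) and set2. z-scoring uses the population-SD convention
computed per trait over *all* tested SNP, not just the selected rows, so
cell values are comparable across rows and breeds. Whether SCS/CM count
as "udder traits" in step 3 was unstated in the source methodology; here
the udder role covers only the five conformation traits.

The three per-breed AWMs are intersected on SNP ids (all seven Venn
regions are reported); how the multi-breed matrices should be merged
before network inference is ambiguous in the literature, so the default
reports per-breed networks plus the three-way common set, and stacking
is left to the user (the matrices share trait columns, so `rbind` of the
`z` components is well-defined).

## 4. PCIT

For every trio $(x, y, z)$ the first-order partial correlations are

$$r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},$$

and the local tolerance is the average shrinkage
$\varepsilon = \tfrac13\left(\frac{r_{xy\cdot z}}{r_{xy}}
 + \frac{r_{xz\cdot y}}{r_{xz}} + \frac{r_{yz\cdot x}}{r_{yz}}\right)$.
The $x$–$y$ edge is non-significant if some $z$ gives
$|r_{xy}| < |\varepsilon\, r_{xz}|$ **and**
$|r_{xy}| < |\varepsilon\, r_{yz}|$.

Numerical rules, all exercised by tests:

* correlations are clamped to $\pm(1-10^{-9})$ before any partial is
  formed, so denominators never vanish and $\varepsilon$ is always
  finite;
* a ratio term whose direct correlation is below $10^{-12}$ in
  magnitude is skipped and $\varepsilon$ averages the remaining terms;
  a trio with all three terms degenerate rejects nothing;
* edges with $r$ exactly 0 are recorded but can never be significant;
  with fewer than three nodes every nonzero edge survives vacuously.

The implementation vectorises over the conditioning node $z$ ($n$
matrix sweeps of $n^2$ entries each); a deliberately naive triple loop
in the test helpers is the correctness oracle and the two agree edge-set
for edge-set on random instances. Enumeration is still $O(n^3)$, so runs
above 3,000 nodes are refused unless forced. Whether PCIT should see
SNP-level or gene-collapsed rows is implied but unstated in the source
methodology; here the nodes are the deduplicated AWM rows — one per gene
plus intergenic SNP — which is also what keeps node counts tractable.

## 5. What the simulator emulates — and what it does not

`simulate_genotypes()` draws an ancestral alternate-allele frequency
uniformly on `maf_range` (default `[0.02, 0.5]`, the near-uniform
spectrum of evaluation SNP chips after MAF filtering), perturbs it per
breed with a Balding–Nichols Beta draw governed by a single F-like
divergence parameter (`fst`, default 0.05, typical of related taurine
breeds), and samples dosages binomially — so within-breed genotypes are
in Hardy–Weinberg proportions and loci are *independent*. Cohort sizes
are unequal by default (`A = 150, B = 100, C = 250` at demo scale)
mirroring the Montbeliarde/Normande/Holstein imbalance.

`simulate_phenotypes()` plants a sparse pleiotropic architecture:
`n_causal` loci receive multivariate-normal effect vectors with
covariance proportional to the target genetic correlation matrix. The
default targets are a published French-cattle table (Montbeliarde
heritabilities on the diagonal, e.g. FUA 0.34, MY 0.50, CM 0.03;
FUA–UB genetic correlation 0.40). Printed correlation tables estimated
entry-by-entry are often slightly indefinite — this one has a smallest
eigenvalue of about −0.025 — so `nearest_correlation()` repairs targets
by eigenvalue clipping and diagonal rescaling (the FUA–UB entry is
unchanged to two decimals; the test suite checks this). Residual
cross-trait correlations default to the same matrix: cows share herd
and management environment across traits, and dairy phenotypic
correlations track genetic ones in sign and rough magnitude; pass
`resid_corr = diag(12)` for independent noise. Residuals are scaled so
the realized variance ratio matches the target heritability exactly in
sample terms. CM is thresholded from its latent liability at the
empirical quantile giving 25% incidence by default (a Bernoulli trait
with SD in the 0.24–0.36 range typical of recorded mastitis).

What is *not* emulated: linkage disequilibrium (loci are independent, so
the "one SNP tags a QTL region" phenomenon and proximal contamination
under LD are absent), pedigree structure, selection, genotyping error
and imputation error. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted parameters under clean
conditions — not performance on real LD-structured cattle data. The
number and effect distribution of causal loci is a free choice
(`n_causal`, default 80 at demo scale), not an inference.

The gene map packs non-overlapping exponential-length genes (mean
15 kb, floor 200 bp) into chromosomes with uniformly random gaps. The
fraction of the genome within 10 kb of a gene — hence the set1/set2
balance — is controlled by gene count and length;
`gene_coverage_fraction()` gives the exact padded-union coverage and
`genes_for_coverage()` inverts it approximately. The demo configuration
(400 genes of mean 15 kb on 5 × 6 Mb) puts roughly half the genome
within 10 kb of a gene so that both annotation classes arise in
quantity.

## 6. Problem sizes used by the checks

Chosen once as the smallest scales at which the quantities of interest
are statistically stable:

* GRM oracle equivalence: random 20 × 50 panels, agreement to 1e-12.
* Null calibration: 500 cows × 2,000 SNP × 50 null traits (pooled
  type-I error within ±0.01 of 0.05); REML recovery of h² = 0.5 over
  200 replicates at n = 500.
* Correlation recovery: 20 replicates of 2,000 cows × 2,000 SNP with
  500 causal loci; the FUA–UB SNP-based correlation is averaged across
  replicates (±0.15 band around the planted 0.40). The acceptance
  script runs a lighter 6 × 1,200-cow version of the same experiment.
* PCIT oracle equivalence: 100 random 15-node matrices, exact edge-set
  identity.
* End-to-end determinism: the demo configuration (500 cows, 1,200 SNP)
  run twice, compared by artifact MD5.

## 7. Known limitations

* Independent-loci simulation cannot probe LD-driven behaviour (tag-SNP
  redundancy, proximal contamination, the 1SNP:1gene rule's real
  purpose); the optional block-copy LD mode was deferred because no LD
  parameters were available to calibrate it against.
* The mixed model fits one variance ratio per trait; traits with
  strongly non-normal yield deviations (CM is 0/1) are handled by the
  linear model, which is conventional but approximate — its p-values
  for CM are calibrated only asymptotically.
* PCIT is cubic in node count; the 3,000-node ceiling is a guardrail,
  not a hard limit.
* `combine_breeds()` intersects on SNP ids and therefore requires a
  shared marker namespace across breeds (true for chip data, not for
  sequence).
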