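#' Default pipeline configuration
#'
#' A single declarative list holding every constant of the analysis:
#' simulation sizes, QC thresholds (call rate 0.99, MAF 0.02, HWE 1e-4),
#' selection thresholds (nominal alpha 0.05, Bonferroni alpha 0.05), the
#' key trait (UDD), the 10-kb gene window and the pleiotropy rule
#' (min_udder 2, min_other data-driven when NULL). Cohort sizes follow
#' the unequal three-breed structure of French dairy data (C largest,
#' standing in for Holstein) at demonstration scale. Round-trips
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param seed Base seed; stage seeds are derived by fixed offsets.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    n_per_breed = c(A = 150L, B = 100L, C = 250L),
    n_snps = 1200L,
    n_chrom = 5L,
    chrom_length = 6e6,
    maf_range = c(0.02, 0.5),
    fst = 0.05,
    n_genes = 400L,
    mean_gene_length = 15000,
    n_causal = 80L,
    cm_incidence = 0.25,
    qc = list(call_rate = 0.99, maf = 0.02, hwe_p = 1e-4),
    alpha = 0.05,
    bonferroni_alpha = 0.05,
    key_trait = "UDD",
    min_other = NULL,
    min_udder = 2L,
    window_bp = 10000L,
    secondary_from_all = FALSE,
    combine_mode = "intersection",
    pcit_max_nodes = 3000L
  ), class = "run_config")
}

#' @rdname default_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  # single-bracket assignment keeps explicit NULLs (e.g. min_other)
  for (k in names(cfg)) base[k] <- list(cfg[[k]])
  # yaml drops names on the cohort vector; restore breed labels
  if (is.null(names(base$n_per_breed))) {
    names(base$n_per_breed) <- LETTERS[seq_along(base$n_per_breed)]
  }
  base
}

#' Run the full simulate - QC/GWAS - AWM - PCIT pipeline
#'
#' Executes every stage per breed under the configuration, writes each
#' interface artifact (VCF + dosage TSV, BED gene map, phenotype and
#' truth tables, QC report, per-breed GRM and association TSVs, AWM CSV
#' with provenance, trait-correlation TSVs, overlap JSON, PCIT edge
#' lists and GraphML, YAML config) under `outdir`, and returns a
#' manifest recording seeds, stage attrition counts and the MD5 hash of
#' every artifact. Identical config + seed give a hash-identical
#' manifest.
#'
#' @param config A [default_config()]-style list.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest (list), invisibly written to
#'   `outdir/manifest.json` as well.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         quiet = FALSE) {
  stopifnot(!missing(outdir))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[awmpcit] ", ...)
  art <- character()
  add_art <- function(path) art <<- c(art, path)
  seeds <- list(genotypes = config$seed + 11L,
                genes = config$seed + 23L,
                phenotypes = config$seed + 37L)

  stage <- "simulate"
  res <- tryCatch({
    say("simulating genotypes: ", sum(config$n_per_breed), " cows x ",
        config$n_snps, " SNP")
    panel <- simulate_genotypes(config$n_per_breed, config$n_snps,
                                n_chrom = config$n_chrom,
                                maf_range = config$maf_range,
                                fst = config$fst,
                                chrom_length = config$chrom_length,
                                seed = seeds$genotypes)
    genes <- simulate_gene_map(config$n_genes,
                               rep(config$chrom_length, config$n_chrom),
                               mean_gene_length = config$mean_gene_length,
                               seed = seeds$genes)
    sim <- simulate_phenotypes(panel, config$n_causal,
                               cm_incidence = config$cm_incidence,
                               seed = seeds$phenotypes)
    add_art(write_vcf(panel, file.path(outdir, "genotypes.vcf"),
                      chrom_length = config$chrom_length))
    add_art(write_dosage_tsv(panel, file.path(outdir, "dosage.tsv")))
    add_art(write_bed(genes, file.path(outdir, "genes.bed")))
    add_art(write_phenotypes_tsv(sim$traits, panel$breed,
                                 file.path(outdir, "phenotypes.tsv")))
    write_truth(sim$truth, file.path(outdir, "truth"))
    add_art(file.path(outdir, "truth.tsv"))
    add_art(file.path(outdir, "truth.json"))

    stage <- "qc"
    qc <- apply_qc(panel, call_rate = config$qc$call_rate,
                   maf = config$qc$maf, hwe_p = config$qc$hwe_p)
    say("QC: ", qc$panel$n_snps, " of ", panel$n_snps, " SNP retained")
    add_art(write_assoc_tsv(qc$report, file.path(outdir, "qc_report.tsv")))

    stage <- "gwas"
    breeds <- names(config$n_per_breed)
    assoc <- list()
    sig_counts <- list()
    for (b in breeds) {
      bp <- panel_subset_breed(qc$panel, b)
      say("GWAS breed ", b, ": ", length(bp$sample_ids), " cows")
      grm <- compute_grm(bp, on_monomorphic = "drop")
      add_art(write_grm_tsv(grm, file.path(outdir,
                                           paste0("grm_", b, ".tsv"))))
      assoc[[b]] <- gwas_scan_traits(bp, sim$traits, breed = b, grm = grm)
      for (tr in names(assoc[[b]])) {
        fn <- file.path(outdir, sprintf("assoc_%s_%s.tsv", b,
                                        gsub("%", "pct", tr)))
        add_art(write_assoc_tsv(assoc[[b]][[tr]], fn))
      }
      sig_counts[[b]] <- vapply(assoc[[b]], function(a) {
        sum(a$p_bonferroni < config$bonferroni_alpha, na.rm = TRUE)
      }, numeric(1))
    }

    stage <- "awm"
    awms <- list()
    for (b in breeds) {
      awms[[b]] <- build_awm(assoc[[b]], genes,
                             key_trait = config$key_trait,
                             alpha = config$alpha,
                             min_other = config$min_other,
                             min_udder = config$min_udder,
                             window = config$window_bp,
                             secondary_from_all = config$secondary_from_all,
                             breed = b)
      say("AWM breed ", b, ": ", nrow(awms[[b]]$z), " rows (set1 ",
          awms[[b]]$counts[["set1"]], " + set2 ",
          awms[[b]]$counts[["set2"]], ")")
      add_art(write_awm_csv(awms[[b]],
                            file.path(outdir, paste0("awm_", b, ".csv")),
                            file.path(outdir,
                                      paste0("awm_", b, "_provenance.tsv"))))
      add_art(write_matrix_tsv(awm_trait_correlations(awms[[b]]),
                               file.path(outdir,
                                         paste0("trait_corr_", b, ".tsv"))))
    }
    overlap <- combine_breeds(awms)
    say("overlap: ", overlap$counts[["ABC"]], " SNP common to all breeds")
    jsonlite::write_json(
      list(counts = as.list(overlap$counts),
           common_snp_ids = overlap$common_snp_ids,
           common_gene_ids = overlap$common_gene_ids),
      file.path(outdir, "overlap.json"), digits = NA, auto_unbox = TRUE)
    add_art(file.path(outdir, "overlap.json"))

    stage <- "pcit"
    nets <- list()
    for (b in breeds) {
      corr <- row_correlations(awms[[b]])
      nets[[b]] <- pcit_filter(corr, max_nodes = config$pcit_max_nodes)
      say("PCIT breed ", b, ": ", nets[[b]]$n_significant,
          " significant edges among ", length(nets[[b]]$nodes), " nodes")
      add_art(write_edges_tsv(nets[[b]],
                              file.path(outdir,
                                        paste0("edges_", b, ".tsv"))))
      add_art(write_graphml(nets[[b]],
                            file.path(outdir,
                                      paste0("network_", b, ".graphml"))))
    }
    add_art(write_config(config, file.path(outdir, "config.yaml")))
    list(panel = panel, genes = genes, sim = sim, qc = qc, assoc = assoc,
         awms = awms, overlap = overlap, nets = nets,
         sig_counts = sig_counts)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), " (partial outputs kept in ", outdir, ")",
         call. = FALSE)
  })

  hashes <- tools::md5sum(sort(art))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    package = "awmpcit",
    config = unclass(config),
    seeds = seeds,
    counts = list(
      n_cows = sum(config$n_per_breed),
      n_snps_simulated = config$n_snps,
      n_snps_qc = res$qc$panel$n_snps,
      significant_snp_bonferroni = res$sig_counts,
      awm = lapply(res$awms, function(a) as.list(a$counts)),
      overlap = as.list(res$overlap$counts),
      pcit_significant_edges = lapply(res$nets,
                                      function(n) n$n_significant)),
    artifacts = as.list(hashes))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Render a report from a completed pipeline run
#'
#' Rebuilds the headline figures from the written artifacts (never from
#' in-memory state): per-breed Manhattan panels for all 12 traits, the
#' MAF spectrum, SNP-based versus true genetic trait-correlation
#' heatmaps, and the multi-breed overlap counts; writes `report.md`
#' summarising the manifest counts (stating explicitly when a network
#' has no significant edges) and, where a PNG device is available, the
#' figures as PNG files.
#'
#' @param outdir Directory of a completed [run_pipeline()] run.
#' @param write_png Write figures as PNGs (default TRUE when the png
#'   device is available).
#' @return List with `plots` (named ggplot objects) and `report_path`.
#' @export
render_report <- function(outdir, write_png = capabilities("png")) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", outdir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  breeds <- names(manifest$counts$awm)
  plots <- list()

  # Manhattan panels: one figure per breed, faceted by trait
  for (b in breeds) {
    files <- list.files(outdir, pattern = paste0("^assoc_", b, "_.*\\.tsv$"),
                        full.names = TRUE)
    if (length(files) == 0) stop("missing association artifacts for ", b)
    dat <- do.call(rbind, lapply(files, function(f) {
      a <- utils::read.delim(f, check.names = FALSE)
      a$trait <- sub("\\.tsv$", "",
                     sub(paste0("^assoc_", b, "_"), "", basename(f)))
      a
    }))
    dat <- dat[!is.na(dat$p_raw), ]
    dat$logp <- -log10(dat$p_raw)
    plots[[paste0("manhattan_", b)]] <-
      ggplot2::ggplot(dat, ggplot2::aes(x = pos / 1e6, y = logp,
                                        colour = factor(chrom))) +
      ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
      ggplot2::facet_wrap(~trait, ncol = 4) +
      ggplot2::labs(title = paste("Breed", b), x = "position (Mb)",
                    y = expression(-log[10](p)))
  }

  # MAF spectrum from the QC report
  qc <- utils::read.delim(file.path(outdir, "qc_report.tsv"),
                          check.names = FALSE)
  maf_cols <- grep("^maf_", colnames(qc), value = TRUE)
  maf_long <- data.frame(
    breed = rep(sub("^maf_", "", maf_cols), each = nrow(qc)),
    maf = unlist(qc[maf_cols], use.names = FALSE))
  plots$maf_spectrum <-
    ggplot2::ggplot(maf_long, ggplot2::aes(x = maf)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::facet_wrap(~breed) +
    ggplot2::labs(x = "minor allele frequency", y = "SNP count")

  # trait correlations: SNP-based per breed vs the simulated truth
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"),
                               simplifyVector = TRUE)
  true_corr <- truth$true_genetic_corr
  heat <- function(m, title) {
    df <- expand.grid(a = rownames(m), b = colnames(m),
                      stringsAsFactors = FALSE)
    df$r <- as.vector(m)
    ggplot2::ggplot(df, ggplot2::aes(a, b, fill = r)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
      ggplot2::labs(title = title, x = NULL, y = NULL) +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
  }
  tn <- trait_names()
  rownames(true_corr) <- colnames(true_corr) <- tn
  plots$true_corr <- heat(true_corr, "true genetic correlations")
  for (b in breeds) {
    m <- read_matrix_tsv(file.path(outdir,
                                   paste0("trait_corr_", b, ".tsv")))
    plots[[paste0("snp_corr_", b)]] <-
      heat(m, paste("SNP-based correlations, breed", b))
  }

  ov <- jsonlite::read_json(file.path(outdir, "overlap.json"),
                            simplifyVector = TRUE)
  edges <- manifest$counts$pcit_significant_edges
  lines <- c(
    "# awmpcit pipeline report", "",
    sprintf("- cows: %s; SNP simulated: %s; SNP after QC: %s",
            manifest$counts$n_cows, manifest$counts$n_snps_simulated,
            manifest$counts$n_snps_qc),
    sprintf("- AWM rows per breed: %s",
            paste(vapply(breeds, function(b)
              sprintf("%s=%s", b, manifest$counts$awm[[b]]$rows),
              character(1)), collapse = ", ")),
    sprintf("- SNP common to all three breeds: %s (mapping %s genes)",
            ov$counts$ABC, length(ov$common_gene_ids %||% character())),
    "")
  for (b in breeds) {
    ne <- edges[[b]]
    lines <- c(lines,
               if (is.null(ne) || ne == 0) {
                 sprintf("- breed %s network: no significant edges", b)
               } else {
                 sprintf("- breed %s network: %s significant edges", b, ne)
               })
  }
  report_path <- file.path(outdir, "report.md")
  writeLines(lines, report_path)

  if (isTRUE(write_png)) {
    for (nm in names(plots)) {
      ggplot2::ggsave(file.path(outdir, paste0(nm, ".png")), plots[[nm]],
                      width = 8, height = 6, dpi = 120)
    }
  }
  invisible(list(plots = plots, report_path = report_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
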