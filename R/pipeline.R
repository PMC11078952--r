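# End-to-end orchestration over the synthetic study: peak landscape ->
# element bank -> annotation -> DEGs + time-series clusters -> EWAS ->
# lead extraction / LD expansion -> element intersection -> motif-disruption
# circuit calls, with a machine-readable JSON summary.

#' Flag SNP positions falling inside elements
#'
#' @param snps tibble with `chrom`, `pos` (1-based).
#' @param elements interval tibble.
#' @return Logical vector per SNP.
#' @export
snps_in_elements <- function(snps, elements) {
  if (nrow(snps) == 0) return(logical(0))
  pts <- intervals(snps$chrom, snps$pos - 1L, snps$pos, sorted = FALSE)
  overlaps_any(pts, elements)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates every input (annotation + genome, peaks, counts, genotypes)
#' from `cfg`, then runs: OCR merging, element classification and
#' annotation, all-pairwise differential expression and fuzzy c-means
#' clustering of the DEG union, variant QC, stratification PCA, additive
#' logistic association, lead extraction and LD expansion, intersection of
#' associated SNPs with the element bank (cis-regulatory SNP candidates) and
#' allele-specific motif-disruption calls on the candidates.
#'
#' @param cfg a [sim_config()].
#' @param th an [angio_thresholds()].
#' @param output_dir optional directory: per-stage TSVs and `summary.json`
#'   are written there.
#' @param run_transcriptome,run_ewas stage toggles.
#' @param fcm_m,fcm_seed fuzzy c-means fuzzifier and seed (seed defaults to
#'   the simulation seed).
#' @return List of class `angio_run`: all stage results plus `summary`, a
#'   named list of headline counts.
#' @export
run_pipeline <- function(cfg = sim_config(), th = angio_thresholds(),
                         output_dir = NULL,
                         run_transcriptome = TRUE, run_ewas = TRUE,
                         fcm_m = 1.25, fcm_seed = cfg$seed) {
  sim <- simulate_annotation(cfg)
  peaks <- simulate_peaks(cfg, sim)
  ocrs <- build_angiogenic_ocrs(peaks$dnase[["H-4"]], peaks$dnase[["H-12"]])
  bank <- classify_cres(ocrs, peaks$k27, peaks$k4)
  bank <- annotate_cre_bank(bank, sim$ann, th)
  bk <- glance.cre_bank(bank)
  summary <- list(
    seed = cfg$seed,
    n_ocrs = nrow(ocrs),
    n_elements = bk$n_elements, n_enhancer = bk$n_enhancer,
    n_promoter = bk$n_promoter, n_bifunctional = bk$n_bifunctional,
    n_unmarked = bk$n_unmarked,
    category_fractions = as.list(table(bank$category) / nrow(bank)),
    n_tss_proximal = sum(bank$proximal),
    n_gene_desert = sum(bank$gene_desert))
  out <- list(config = cfg, thresholds = th, sim = sim, peaks = peaks,
              ocrs = ocrs, bank = bank)

  if (run_transcriptome) {
    sc <- simulate_counts(cfg)
    de <- all_pairwise_de(sc$counts, sc$stages, th)
    degs <- union_degs(de)
    prof <- standardize_profiles(stage_profiles(sc$counts, sc$stages, degs))
    fit <- fuzzy_cmeans(prof, c = th$mfuzz_c, m = fcm_m, seed = fcm_seed)
    peak_stage <- cluster_peak_stage(fit)
    per_cluster <- as.list(setNames(tabulate(fit$hard_label, fit$c),
                                    paste0("cluster_", peak_stage)))
    summary$n_degs <- length(degs)
    summary$degs_per_cluster <- per_cluster
    out$counts <- sc; out$de_tables <- de; out$degs <- degs; out$fcm <- fit
    out$expression_pca <- expression_pca(log2(compute_cpm(sc$counts) + 1))
  }

  if (run_ewas) {
    gsim <- simulate_genotypes(cfg, sim)
    qc <- variant_qc(gsim$study, th)
    pca <- genotype_pca(qc$study)
    assoc <- assoc_logistic_additive(qc$study)
    lead <- extract_leads_and_expand(assoc, qc$study, th)
    cand_flag <- snps_in_elements(lead$associated, bank)
    candidates <- lead$associated[cand_flag, ]
    circuits <- candidate_circuits(candidates, bank, gsim$study, sim$genome,
                                   list(sim$motif))
    summary$n_variants_input <- nrow(gsim$study$variants)
    summary$qc_exclusions <- as.list(qc$exclusions)
    summary$n_variants_pass <- nrow(qc$study$variants)
    summary$n_exome_wide <- nrow(lead$exome_wide)
    summary$n_leads <- nrow(lead$leads)
    summary$n_ld_snps <- nrow(lead$ld_snps)
    summary$n_associated <- nrow(lead$associated)
    summary$n_candidates <- nrow(candidates)
    summary$n_circuits <- sum(circuits$disrupted)
    summary$circuit_tfs <- unique(circuits$tf[circuits$disrupted])
    out$genotypes <- gsim; out$qc <- qc; out$genotype_pca <- pca
    out$assoc <- assoc; out$lead_expansion <- lead
    out$candidates <- candidates; out$circuits <- circuits
  }

  out$summary <- summary
  class(out) <- "angio_run"
  if (!is.null(output_dir)) write_run_outputs(out, output_dir)
  out
}

# Disruption calls for every (candidate SNP, covering element, PWM) triple.
candidate_circuits <- function(candidates, bank, gs, genome, pwms) {
  empty <- tibble(snp_id = character(), element_id = character(),
                  tf = character(), ref_best = numeric(),
                  alt_best = numeric(), delta = numeric(),
                  disrupted = logical(), direction = character(),
                  strand = character(), offset = integer(), edge = logical())
  if (nrow(candidates) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    v <- gs$variants[gs$variants$snp_id == candidates$snp_id[i], ]
    if (nrow(v) == 0) next
    hit <- bank$chrom == v$chrom & bank$start <= v$pos - 1L & bank$end > v$pos - 1L
    for (e in which(hit)) {
      for (p in pwms) {
        rows[[length(rows) + 1]] <- snp_disruption(
          as.list(v[1, ]), bank[e, ], genome, p)
      }
    }
  }
  if (!length(rows)) return(empty)
  bind_rows(rows)
}

#' @export
print.angio_run <- function(x, ...) {
  s <- x$summary
  cat("<angio_run>\n")
  cat(sprintf("  OCRs: %d; elements: %d (%d bifunctional)\n",
              s$n_ocrs, s$n_elements, s$n_bifunctional))
  if (!is.null(s$n_degs))
    cat(sprintf("  DEGs: %d in %d clusters\n", s$n_degs,
                length(s$degs_per_cluster)))
  if (!is.null(s$n_associated))
    cat(sprintf("  SNPs: %d exome-wide, %d leads, %d associated, %d candidates, %d circuit(s)\n",
                s$n_exome_wide, s$n_leads, s$n_associated, s$n_candidates,
                s$n_circuits))
  invisible(x)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(run$ocrs, file.path(dir, "ocrs.bed"))
  readr::write_tsv(as_tibble(run$bank), file.path(dir, "cre_bank.tsv"))
  if (!is.null(run$degs)) {
    readr::write_lines(run$degs, file.path(dir, "degs.txt"))
    readr::write_tsv(tidy.angio_fcm(run$fcm), file.path(dir, "memberships.tsv"))
  }
  if (!is.null(run$assoc)) {
    readr::write_tsv(run$assoc, file.path(dir, "association.tsv"))
    readr::write_tsv(run$lead_expansion$associated,
                     file.path(dir, "associated_snps.tsv"))
    readr::write_tsv(run$candidates, file.path(dir, "cis_regulatory_candidates.tsv"))
    readr::write_tsv(run$circuits, file.path(dir, "circuits.tsv"))
  }
  # resolved config + summary for provenance
  cfg <- run$config
  jsonlite::write_json(cfg[names(cfg) != "chrom_sizes"],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
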