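#' Analysis thresholds
#'
#' Central container for every cutoff the pipeline uses. Defaults follow the
#' published analysis conventions for this workflow: differential expression
#' at |log2FC| >= 0.58 and BH-adjusted p <= 0.01; exome-wide association at
#' p < 1e-5; lead-SNP independence at r^2 < 0.6 and LD expansion at
#' r^2 > 0.2; variant QC at control MAF >= 0.05, call rate >= 0.95 and
#' control HWE exact p >= 1e-5; TSS-proximal elements within 5 kb; gene
#' deserts beyond 500 kb; motif enrichment significance at p < 1e-20;
#' region (gene-set) enrichment at p < 0.05; four time-series clusters.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `angio_thresholds`.
#' @examples
#' th <- angio_thresholds(deg_padj = 0.05)
#' th$deg_log2fc
#' @export
angio_thresholds <- function(...) {
  th <- list(
    deg_log2fc      = 0.58,
    deg_padj        = 0.01,
    assoc_p         = 1e-5,
    lead_r2         = 0.6,
    expand_r2       = 0.2,
    maf_min         = 0.05,
    call_rate_min   = 0.95,
    hwe_p_min       = 1e-5,
    tss_proximal_kb = 5,
    gene_desert_kb  = 500,
    motif_enrich_p  = 1e-20,
    great_p         = 0.05,
    mfuzz_c         = 4L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(th))
  if (length(bad)) abort(paste0("unknown threshold(s): ", paste(bad, collapse = ", ")))
  th[names(dots)] <- dots
  stopifnot(all(vapply(th, function(x) is.numeric(x) && x > 0, logical(1))))
  stopifnot(th$lead_r2 > 0, th$lead_r2 < 1, th$expand_r2 > 0, th$expand_r2 < 1)
  structure(th, class = c("angio_thresholds", "list"))
}
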