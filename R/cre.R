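# Building the angiogenic open-chromatin-region set and the cis-regulatory
# element bank: OCRs = merged late-stage DNase peaks; elements = OCRs carrying
# enhancer (H3K27ac) and/or promoter (H3K4me3) histone marks.

#' Merge late-stage open chromatin regions
#'
#' Unions the DNase-seq peak sets of the two late stimulation timepoints and
#' merges touching/overlapping peaks into one set of open chromatin regions.
#'
#' @param dnase_h4,dnase_h12 interval tibbles of DNase peaks.
#' @param min_gap merge gap passed to [merge_intervals()].
#' @return Sorted interval tibble of OCRs.
#' @export
build_angiogenic_ocrs <- function(dnase_h4, dnase_h12, min_gap = 0L) {
  if (nrow(dnase_h4) == 0 || nrow(dnase_h12) == 0)
    warn("one DNase peak set is empty; OCRs built from the other alone")
  both <- bind_rows(dnase_h4[c("chrom", "start", "end")],
                    dnase_h12[c("chrom", "start", "end")])
  merge_intervals(both, min_gap = min_gap)
}

#' Classify OCRs into cis-regulatory elements
#'
#' An OCR gets `enhancer = TRUE` if it overlaps an H3K27ac peak in any
#' sample, `promoter = TRUE` if it overlaps an H3K4me3 peak in any sample.
#' OCRs with neither mark are excluded from the bank (their count is kept as
#' an attribute).
#'
#' @param ocrs interval tibble from [build_angiogenic_ocrs()].
#' @param k27_by_sample,k4_by_sample lists of interval tibbles (one per
#'   sample) of H3K27ac and H3K4me3 peaks.
#' @param min_overlap minimum shared bases for a mark to count (default 1).
#' @return A `cre_bank` tibble: `chrom`, `start`, `end`, `element_id`,
#'   `enhancer`, `promoter`, `bifunctional`; attributes `n_ocrs` and
#'   `n_unmarked` record the input size and exclusions.
#' @export
classify_cres <- function(ocrs, k27_by_sample, k4_by_sample, min_overlap = 1L) {
  validate_intervals(ocrs, "OCRs")
  flag_any <- function(sets) {
    f <- rep(FALSE, nrow(ocrs))
    for (s in sets) f <- f | overlaps_any(ocrs, s, min_overlap = min_overlap)
    f
  }
  enh <- flag_any(k27_by_sample)
  pro <- flag_any(k4_by_sample)
  keep <- enh | pro
  bank <- ocrs[keep, c("chrom", "start", "end")]
  bank <- mutate(bank,
                 element_id = sprintf("CRE%05d", row_number()),
                 enhancer = enh[keep], promoter = pro[keep],
                 bifunctional = enh[keep] & pro[keep])
  attr(bank, "n_ocrs") <- nrow(ocrs)
  attr(bank, "n_unmarked") <- sum(!keep)
  class(bank) <- c("cre_bank", class(bank))
  bank
}

#' Annotate a CRE bank with genomic context
#'
#' Adds the mutually exclusive genomic category, signed nearest-TSS distance,
#' nearest gene, TSS-proximal flag and gene-desert flag.
#'
#' @param bank a `cre_bank` from [classify_cres()].
#' @param ann a [gene_annotation()].
#' @param th thresholds.
#' @param promoter_window promoter window (bp) for [annotate_category()].
#' @return The bank with columns `category`, `tss_distance`, `nearest_gene`,
#'   `proximal`, `gene_desert` added.
#' @export
annotate_cre_bank <- function(bank, ann, th = angio_thresholds(),
                              promoter_window = 3000L) {
  cls <- class(bank)
  bank$category <- annotate_category(bank, ann, promoter_window)
  prof <- tss_profile(bank, ann, th)
  bank$tss_distance <- prof$per_element$tss_distance
  bank$nearest_gene <- prof$per_element$nearest_gene
  bank$proximal <- prof$per_element$proximal
  bank$gene_desert <- prof$per_element$gene_desert
  class(bank) <- cls
  attr(bank, "tss_histogram") <- prof$histogram
  bank
}

#' Summarise a CRE bank
#'
#' @param object a `cre_bank`.
#' @param ... unused.
#' @return One-row tibble with element counts, flag counts and (when the bank
#'   is annotated) category fractions.
#' @method glance cre_bank
#' @export
glance.cre_bank <- function(object, ...) {
  out <- tibble(n_ocrs = attr(object, "n_ocrs") %||% NA_integer_,
                n_elements = nrow(object),
                n_enhancer = sum(object$enhancer),
                n_promoter = sum(object$promoter),
                n_bifunctional = sum(object$bifunctional),
                n_unmarked = attr(object, "n_unmarked") %||% NA_integer_)
  if ("category" %in% names(object)) {
    fr <- table(factor(object$category,
                       levels = c("promoter", "exon", "intron",
                                  "UTR5/UTR3", "intergenic"))) / nrow(object)
    out <- bind_cols(out, as_tibble(as.list(setNames(
      as.numeric(fr),
      c("frac_promoter", "frac_exon", "frac_intron", "frac_utr",
        "frac_intergenic")))))
    out$n_proximal <- sum(object$proximal)
    out$n_gene_desert <- sum(object$gene_desert)
  }
  out
}

#' @export
print.cre_bank <- function(x, ...) {
  cat(sprintf("<cre_bank> %d elements (%d enhancer, %d promoter, %d bifunctional)\n",
              nrow(x), sum(x$enhancer), sum(x$promoter), sum(x$bifunctional)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
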