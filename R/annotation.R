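# Gene annotation container and genomic-context annotation of elements/SNPs.

#' Assemble a gene annotation object
#'
#' @param genes tibble with columns `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `tss` (TSS position), `start`, `end` (gene body, 0-based half-open).
#' @param exons,utr5,utr3 interval tibbles with an extra `gene_id` column;
#'   may be empty.
#'
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(genes,
                            exons = empty_feature(),
                            utr5 = empty_feature(),
                            utr3 = empty_feature()) {
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  stopifnot(all(need %in% names(genes)))
  if (nrow(genes)) {
    stopifnot(all(genes$strand %in% c("+", "-")))
    stopifnot(all(genes$tss >= genes$start & genes$tss <= genes$end))
  }
  for (f in list(exons, utr5, utr3)) {
    validate_intervals(f, "feature set")
    stopifnot("gene_id" %in% names(f))
  }
  structure(list(genes = as_tibble(genes), exons = as_tibble(exons),
                 utr5 = as_tibble(utr5), utr3 = as_tibble(utr3)),
            class = "gene_annotation")
}

empty_feature <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         gene_id = character())
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes, %d exons, %d UTR5, %d UTR3\n",
              nrow(x$genes), nrow(x$exons), nrow(x$utr5), nrow(x$utr3)))
  invisible(x)
}

#' TSS table of an annotation
#' @param ann a `gene_annotation`.
#' @return tibble with `chrom`, `pos`, `strand`, `gene_id`.
#' @export
tss_table <- function(ann) {
  tibble(chrom = ann$genes$chrom, pos = ann$genes$tss,
         strand = ann$genes$strand, gene_id = ann$genes$gene_id)
}

#' Assign each element one genomic category
#'
#' Categories are mutually exclusive with fixed priority
#' promoter > UTR5/UTR3 > exon > intron > intergenic. Promoter means overlap
#' with the window `tss +/- promoter_window`; intron means inside a gene body
#' but hitting no exon/UTR.
#'
#' @param elements interval tibble.
#' @param ann a [gene_annotation()].
#' @param promoter_window half-width (bp) of the promoter window around each
#'   TSS (default 3000).
#' @return Character vector of categories (`"promoter"`, `"UTR5/UTR3"`,
#'   `"exon"`, `"intron"`, `"intergenic"`), one per element.
#' @export
annotate_category <- function(elements, ann, promoter_window = 3000L) {
  stopifnot(promoter_window > 0)
  validate_intervals(elements, "elements")
  n <- nrow(elements)
  if (n == 0) return(character(0))
  g <- ann$genes
  prom <- if (nrow(g)) intervals(g$chrom, pmax(0L, g$tss - promoter_window),
                                 g$tss + promoter_window, sorted = FALSE)
          else empty_feature()[1:3]
  body <- if (nrow(g)) intervals(g$chrom, g$start, g$end, sorted = FALSE)
          else empty_feature()[1:3]
  utr <- bind_rows(ann$utr5, ann$utr3)
  cat <- rep("intergenic", n)
  in_body <- overlaps_any(elements, body)
  cat[in_body] <- "intron"
  if (nrow(ann$exons)) cat[overlaps_any(elements, ann$exons)] <- "exon"
  if (nrow(utr))       cat[overlaps_any(elements, utr)] <- "UTR5/UTR3"
  if (nrow(prom))      cat[overlaps_any(elements, prom)] <- "promoter"
  cat
}

#' TSS distance profile of an element bank
#'
#' Flags each element as TSS-proximal (|distance| <= `tss_proximal_kb`) or
#' gene-desert (distance to the nearest gene body > `gene_desert_kb`), and
#' bins distances into <=5 kb, 5-100 kb, 100-500 kb and >500 kb.
#'
#' @param elements interval tibble.
#' @param ann a [gene_annotation()].
#' @param th an [angio_thresholds()] list.
#' @return List with `per_element` (tibble adding `tss_distance`,
#'   `nearest_gene`, `proximal`, `gene_desert`), `histogram` (tibble of bin
#'   counts over elements with defined distance) and `n_undefined`.
#' @export
tss_profile <- function(elements, ann, th = angio_thresholds()) {
  nd <- nearest_tss_distance(elements, tss_table(ann))
  prox_bp <- th$tss_proximal_kb * 1000
  desert_bp <- th$gene_desert_kb * 1000
  # gene-desert test uses distance to the nearest gene BODY, not the TSS
  gene_dist <- rep(NA_real_, nrow(elements))
  g <- ann$genes
  if (nrow(g) && nrow(elements)) {
    mid <- nd$midpoint
    for (i in seq_len(nrow(elements))) {
      same <- g$chrom == elements$chrom[i]
      if (!any(same)) next
      d <- pmax(0, pmax(g$start[same] - mid[i], mid[i] - (g$end[same] - 1L)))
      gene_dist[i] <- min(d)
    }
  }
  per <- mutate(nd,
                proximal    = !is.na(.data$tss_distance) & abs(.data$tss_distance) <= prox_bp,
                gene_desert = !is.na(gene_dist) & gene_dist > desert_bp)
  ok <- !is.na(per$tss_distance)
  ad <- abs(per$tss_distance[ok])
  bins <- cut(ad, breaks = c(-1, prox_bp, 1e5, desert_bp, Inf),
              labels = c("<=5kb", "5-100kb", "100-500kb", ">500kb"))
  hist <- as_tibble(table(bin = bins), .name_repair = "minimal")
  names(hist) <- c("bin", "n")
  list(per_element = per, histogram = hist, n_undefined = sum(!ok))
}

#' Gene regulatory domains (basal plus extension)
#'
#' Each gene gets a basal domain (5 kb upstream, 1 kb downstream of its TSS,
#' strand-aware) extended in both directions up to `extension` bp but not
#' into the nearest neighbouring basal domain.
#'
#' @param ann a [gene_annotation()].
#' @param basal_up,basal_down basal domain extents (bp) upstream/downstream.
#' @param extension maximal extension (bp), default 1 Mb.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @return Interval tibble with a `gene_id` column.
#' @export
regulatory_domains <- function(ann, basal_up = 5000L, basal_down = 1000L,
                               extension = 1e6, chrom_sizes = NULL) {
  g <- ann$genes
  if (nrow(g) == 0) return(empty_feature())
  up <- ifelse(g$strand == "+", g$tss - basal_up, g$tss - basal_down)
  dn <- ifelse(g$strand == "+", g$tss + basal_down, g$tss + basal_up)
  basal_start <- pmax(0, up)
  basal_end <- dn
  out <- vector("list", length(unique(g$chrom)))
  k <- 0
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    ord <- idx[order(g$tss[idx])]
    bs <- basal_start[ord]; be <- basal_end[ord]
    ext_start <- pmax(0, g$tss[ord] - extension)
    ext_end <- g$tss[ord] + extension
    n <- length(ord)
    # extension stops at the neighbour's basal domain
    if (n > 1) {
      ext_start[-1] <- pmax(ext_start[-1], be[-n])
      ext_end[-n] <- pmin(ext_end[-n], bs[-1])
    }
    dom_start <- pmin(bs, ext_start)
    dom_end <- pmax(be, ext_end)
    if (!is.null(chrom_sizes) && ch %in% names(chrom_sizes))
      dom_end <- pmin(dom_end, chrom_sizes[[ch]])
    out[[k <- k + 1]] <- tibble(chrom = ch, start = as.integer(dom_start),
                                end = as.integer(dom_end),
                                gene_id = g$gene_id[ord])
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Region-based gene-set enrichment (binomial test)
#'
#' For each gene set, merges the member genes' regulatory domains, computes
#' the genome fraction pi they cover, counts elements whose midpoint-bearing
#' interval overlaps the merged domains, and reports the upper binomial tail
#' P(X >= k) with n = number of elements.
#'
#' @param elements interval tibble.
#' @param gene_sets named list of character vectors of gene ids.
#' @param domains regulatory domain tibble from [regulatory_domains()].
#' @param genome_size total genome length (bp).
#' @param th thresholds (significance at `great_p`).
#' @return Tibble with `set`, `n_elements`, `k_hits`, `pi`, `p`, `significant`.
#' @export
region_enrichment_binomial <- function(elements, gene_sets, domains,
                                       genome_size, th = angio_thresholds()) {
  validate_intervals(elements, "elements")
  stopifnot(genome_size > 0)
  n <- nrow(elements)
  res <- purrr::imap(gene_sets, function(gs, nm) {
    dom <- domains[domains$gene_id %in% gs, c("chrom", "start", "end")]
    dom <- merge_intervals(dom)
    covered <- sum(as.numeric(dom$end - dom$start))
    if (covered > genome_size)
      abort("merged domains exceed genome size")
    pi <- covered / genome_size
    k <- if (nrow(dom)) sum(overlaps_any(elements, dom)) else 0L
    if (pi == 0 && k > 0)
      abort(sprintf("set %s: zero domain coverage but %d hits", nm, k))
    p <- if (k == 0) 1 else pbinom(k - 1, n, pi, lower.tail = FALSE)
    tibble(set = nm, n_elements = n, k_hits = as.integer(k), pi = pi, p = p)
  })
  mutate(bind_rows(res), significant = .data$p < th$great_p)
}

#' Categorise SNP positions against gene annotation
#'
#' Priority exon > UTR > intron > intergenic. Positions are 1-based and
#' converted to half-open points internally.
#'
#' @param snps tibble with `chrom`, `pos` (1-based).
#' @param ann a [gene_annotation()].
#' @param with_utr report a separate `"UTR"` category (default `FALSE`:
#'   UTR positions count as exonic sequence context is not separated).
#' @return Character vector of categories per SNP.
#' @export
annotate_snps <- function(snps, ann, with_utr = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (nrow(snps) == 0) return(character(0))
  pts <- intervals(snps$chrom, snps$pos - 1L, snps$pos, sorted = FALSE)
  g <- ann$genes
  body <- if (nrow(g)) intervals(g$chrom, g$start, g$end, sorted = FALSE)
          else empty_feature()[1:3]
  utr <- bind_rows(ann$utr5, ann$utr3)
  cat <- rep("intergenic", nrow(snps))
  if (nrow(body)) cat[overlaps_any(pts, body)] <- "intron"
  if (nrow(utr)) cat[overlaps_any(pts, utr)] <- if (with_utr) "UTR" else "exon"
  if (nrow(ann$exons)) cat[overlaps_any(pts, ann$exons)] <- "exon"
  cat
}
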