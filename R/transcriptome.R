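# Expression normalisation, differential expression over the four-stage
# VEGFA stimulation time course, and sample-level PCA.
#
# Counts enter as a genes x samples table; `stages` labels each sample with
# its timepoint (H-0, H-1, H-4, H-12 in the reference design, n = 2 each).

# Accepts a numeric matrix with rownames, or a data frame whose first column
# is the gene id. Returns list(mat, genes).
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    genes <- as.character(counts[[1]])
    mat <- as.matrix(counts[-1])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(counts)
    if (is.null(rownames(mat)))
      rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  if (any(mat < 0)) abort("negative counts")
  mat
}

#' Counts per million
#'
#' @param counts genes x samples count matrix (or data frame with a gene-id
#'   first column).
#' @return Matrix of CPM values; every column sums to 1e6.
#' @examples
#' compute_cpm(matrix(c(10, 90), 2, dimnames = list(c("a", "b"), "s1")))
#' @export
compute_cpm <- function(counts) {
  mat <- as_count_matrix(counts)
  tot <- colSums(mat)
  if (any(tot == 0))
    abort(paste0("zero total count in sample(s): ",
                 paste(colnames(mat)[tot == 0], collapse = ", ")))
  sweep(mat, 2, tot, "/") * 1e6
}

# DESeq-style median-of-ratios size factors over genes positive in all samples
size_factors <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) abort("no gene with all-positive counts; cannot normalise")
  logs <- log(mat[pos, , drop = FALSE])
  ref <- rowMeans(logs)
  exp(apply(logs - ref, 2, stats::median))
}

# Method-of-moments common NB dispersion from within-stage replicate scatter,
# floored at `floor`. The per-gene moment estimates are averaged (not
# medianed): with few replicates the sample variance is strongly
# right-skewed, so the median would underestimate the dispersion.
common_dispersion <- function(norm, stages, floor = 0.01) {
  ug <- unique(stages)
  alphas <- c()
  for (s in ug) {
    sub <- norm[, stages == s, drop = FALSE]
    if (ncol(sub) < 2) next
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ok <- mu > 5
    if (any(ok)) alphas <- c(alphas, (v[ok] - mu[ok]) / mu[ok]^2)
  }
  if (!length(alphas)) return(floor)
  max(floor, mean(alphas, na.rm = TRUE))
}

#' Pairwise differential expression (negative-binomial Wald test)
#'
#' Library sizes are normalised with median-of-ratios size factors; the
#' per-gene log2 fold change contrasts normalised stage means; the Wald
#' statistic uses an NB variance with a method-of-moments common dispersion
#' (floored at 0.01); p-values are BH-adjusted. A gene is flagged as
#' differentially expressed when |log2FC| >= `th$deg_log2fc` and
#' padj <= `th$deg_padj`.
#'
#' @param counts genes x samples counts.
#' @param stages character vector labelling each sample's stage.
#' @param stage_a,stage_b the two stages to contrast (fold change is B vs A).
#' @param th thresholds.
#' @return Tibble: `gene_id`, `mean_a`, `mean_b`, `log2fc`, `stat`, `p`,
#'   `padj`, `deg`.
#' @export
differential_expression <- function(counts, stages, stage_a, stage_b,
                                    th = angio_thresholds()) {
  mat <- as_count_matrix(counts)
  stopifnot(length(stages) == ncol(mat))
  for (s in c(stage_a, stage_b))
    if (!s %in% stages) abort(paste0("stage not in data: ", s))
  sel <- stages %in% c(stage_a, stage_b)
  mat <- mat[, sel, drop = FALSE]
  st <- stages[sel]
  if (sum(st == stage_a) < 2 || sum(st == stage_b) < 2)
    abort("need >= 2 replicates per stage")
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  alpha <- common_dispersion(norm, st)
  mu_a <- rowMeans(norm[, st == stage_a, drop = FALSE])
  mu_b <- rowMeans(norm[, st == stage_b, drop = FALSE])
  n_a <- sum(st == stage_a); n_b <- sum(st == stage_b)
  eps <- 0.5
  beta <- log(mu_b + eps) - log(mu_a + eps)          # natural-log fold change
  v <- (1 / pmax(mu_a, eps) + alpha) / n_a +
       (1 / pmax(mu_b, eps) + alpha) / n_b
  z <- beta / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  padj <- p.adjust(p, method = "BH")
  log2fc <- beta / log(2)
  tibble(gene_id = rownames(mat), mean_a = unname(mu_a),
         mean_b = unname(mu_b), log2fc = unname(log2fc),
         stat = unname(z), p = unname(p), padj = unname(padj),
         deg = unname(abs(log2fc) >= th$deg_log2fc & padj <= th$deg_padj))
}

#' All pairwise differential-expression contrasts
#'
#' @inheritParams differential_expression
#' @param consecutive_only contrast only consecutive stages in the order
#'   given by `unique(stages)` (default `FALSE`: all pairs).
#' @return Named list of DEG tables, one per contrast ("A_vs_B").
#' @export
all_pairwise_de <- function(counts, stages, th = angio_thresholds(),
                            consecutive_only = FALSE) {
  ug <- unique(stages)
  pairs <- if (consecutive_only) {
    purrr::map(seq_len(length(ug) - 1), ~ c(ug[.x], ug[.x + 1]))
  } else {
    utils::combn(ug, 2, simplify = FALSE)
  }
  out <- purrr::map(pairs, ~ differential_expression(counts, stages,
                                                     .x[1], .x[2], th))
  names(out) <- purrr::map_chr(pairs, ~ paste0(.x[1], "_vs_", .x[2]))
  out
}

#' Union of differentially expressed genes across contrasts
#'
#' @param tables list of DEG tables from [differential_expression()].
#' @return Character vector of gene ids flagged in at least one contrast.
#' @export
union_degs <- function(tables) {
  stopifnot(length(tables) >= 1)
  sort(unique(unlist(purrr::map(tables, ~ .x$gene_id[.x$deg]))))
}

#' Standardise per-gene temporal profiles
#'
#' Row-wise z-scoring (mean 0, sd 1 across stages); genes with zero variance
#' across stages are dropped with a warning.
#'
#' @param expr genes x stages numeric matrix (e.g. stage-mean log2 CPM).
#' @return Standardised matrix (possibly fewer rows).
#' @export
standardize_profiles <- function(expr) {
  mat <- as.matrix(expr)
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  drop <- s == 0 | is.na(s)
  if (any(drop))
    warn(sprintf("dropping %d zero-variance profile(s)", sum(drop)))
  mat <- mat[!drop, , drop = FALSE]
  (mat - mu[!drop]) / s[!drop]
}

#' Stage-mean log2 normalised-count profiles for a gene set
#'
#' Counts are normalised with median-of-ratios size factors rather than CPM:
#' when many genes change between stages, per-million scaling shifts every
#' gene's profile by the stage's library-composition offset, whereas the
#' median ratio tracks the non-changing majority and preserves temporal
#' shapes.
#'
#' @param counts genes x samples counts.
#' @param stages stage label per sample.
#' @param genes gene ids to keep (default all).
#' @return genes x stages matrix of mean log2(normalised count + 1).
#' @export
stage_profiles <- function(counts, stages, genes = NULL) {
  mat <- as_count_matrix(counts)
  norm <- sweep(mat, 2, size_factors(mat), "/")
  if (!is.null(genes)) norm <- norm[rownames(norm) %in% genes, , drop = FALSE]
  lc <- log2(norm + 1)
  ug <- unique(stages)
  out <- vapply(ug, function(s) rowMeans(lc[, stages == s, drop = FALSE]),
                numeric(nrow(lc)))
  colnames(out) <- ug
  out
}

#' Sample-level expression PCA
#'
#' Genes are centred; samples are projected on the first two principal
#' components.
#'
#' @param log_cpm genes x samples matrix (e.g. `log2(compute_cpm(x) + 1)`).
#' @return List of class `angio_pca`: `coords` tibble (`sample`, `PC1`,
#'   `PC2`) and `var_explained` (length-2 fractions).
#' @export
expression_pca <- function(log_cpm) {
  mat <- as.matrix(log_cpm)
  if (ncol(mat) < 2) abort("need >= 2 samples")
  keep <- apply(mat, 1, sd) > 0
  pc <- prcomp(t(mat[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  coords <- tibble(sample = colnames(mat),
                   PC1 = pc$x[, 1],
                   PC2 = if (k >= 2) pc$x[, 2] else 0)
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  structure(list(coords = coords, var_explained = ve), class = "angio_pca")
}

#' @export
print.angio_pca <- function(x, ...) {
  cat(sprintf("<angio_pca> %d samples; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$coords), 100 * x$var_explained[1],
              100 * x$var_explained[min(2, length(x$var_explained))]))
  invisible(x)
}
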