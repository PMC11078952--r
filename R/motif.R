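# Position-weight-matrix machinery: JASPAR PFM parsing, log-odds transform,
# best-hit scanning, element-level motif enrichment, and allele-specific
# SNP motif-disruption calls (SNP-TF circuits).

BASES <- c("A", "C", "G", "T")

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2016+ text format: a `>ID NAME` header followed by four
#' rows `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]` in any row order.
#'
#' @param path path to a JASPAR PFM text file (may hold several records).
#' @return List of `pwm` objects (counts only; see [to_log_odds()]).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) abort("no JASPAR record header ('>') found")
  ends <- c(starts[-1] - 1, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    parts <- strsplit(header, "[ \t]+")[[1]]
    tf <- if (length(parts) >= 2) parts[2] else parts[1]
    body <- lines[(s + 1):e]
    if (length(body) != 4) abort(paste0(tf, ": expected 4 matrix rows"))
    rows <- purrr::map(body, function(ln) {
      lab <- toupper(sub("^([ACGTacgt]).*", "\\1", ln))
      if (!lab %in% BASES) abort(paste0(tf, ": unlabelled matrix row"))
      nums <- suppressWarnings(as.numeric(
        strsplit(gsub("^[ACGTacgt][: ]*\\[?|\\]$", "", ln), "[ \t]+")[[1]] |>
          (\(x) x[nzchar(x)])()))
      if (anyNA(nums)) abort(paste0(tf, ": non-numeric count"))
      if (any(nums < 0)) abort(paste0(tf, ": negative count"))
      list(lab = lab, nums = nums)
    })
    labs <- purrr::map_chr(rows, "lab")
    if (!setequal(labs, BASES)) abort(paste0(tf, ": need one row per base"))
    lens <- purrr::map_int(rows, ~ length(.x$nums))
    if (length(unique(lens)) != 1) abort(paste0(tf, ": rows of unequal length"))
    counts <- do.call(rbind, purrr::map(rows, "nums"))
    rownames(counts) <- labs
    counts <- counts[BASES, , drop = FALSE]
    if (any(colSums(counts) <= 0)) abort(paste0(tf, ": zero column sum"))
    structure(list(tf_name = tf, counts = counts, log_odds = NULL),
              class = "pwm")
  })
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d%s\n", x$tf_name, ncol(x$counts),
              if (is.null(x$log_odds)) " (counts only)" else ""))
  invisible(x)
}

#' Log-odds transform of a PFM
#'
#' `log_odds[b, j] = log2(((counts[b, j] + pc * bg[b]) / (colsum_j + pc)) / bg[b])`.
#'
#' @param pwm a `pwm` from [read_jaspar()].
#' @param background base frequencies (A, C, G, T), summing to 1, all > 0.
#' @param pseudocount total pseudocount (> 0) spread by background.
#' @return The `pwm` with a `log_odds` matrix attached.
#' @export
to_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 1) {
  stopifnot(abs(sum(background) - 1) < 1e-9, all(background > 0),
            pseudocount > 0)
  cs <- colSums(pwm$counts)
  freq <- sweep(pwm$counts + pseudocount * background, 2, cs + pseudocount, "/")
  pwm$log_odds <- log2(freq / background)
  rownames(pwm$log_odds) <- BASES
  pwm
}

#' Consensus score of a PWM
#' @param pwm a `pwm` with log-odds.
#' @return Maximum achievable scan score (sum of column maxima).
#' @export
consensus_score <- function(pwm) {
  stopifnot(!is.null(pwm$log_odds))
  sum(apply(pwm$log_odds, 2, max))
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# score matrix rows for a character vector of bases; N contributes 0
score_window <- function(lo, bases) {
  idx <- match(bases, BASES)
  s <- 0
  for (j in seq_along(bases)) if (!is.na(idx[j])) s <- s + lo[idx[j], j]
  unname(s)
}

#' Best PWM hit in a sequence (both strands)
#'
#' Scans every offset of `seq` and its reverse complement; ties break to the
#' smallest offset, plus strand first.
#'
#' @param pwm a `pwm` with log-odds.
#' @param seq DNA string (alphabet ACGTN; N scores 0).
#' @return List: `score`, `position` (1-based offset on the forward
#'   sequence), `strand` (`"+"`/`"-"`).
#' @export
scan_best <- function(pwm, seq) {
  stopifnot(!is.null(pwm$log_odds))
  seq <- toupper(seq)
  L <- ncol(pwm$log_odds)
  n <- nchar(seq)
  if (n < L) abort("sequence shorter than motif")
  fwd <- strsplit(seq, "")[[1]]
  rev <- strsplit(revcomp(seq), "")[[1]]
  best <- list(score = -Inf, position = NA_integer_, strand = NA_character_)
  # offset-major scan: ties keep the smallest forward offset, and the plus
  # strand at the same offset; the tolerance keeps summation-order rounding
  # from breaking ties inconsistently
  tol <- 1e-9
  for (off in seq_len(n - L + 1)) {
    s <- score_window(pwm$log_odds, fwd[off:(off + L - 1)])
    if (s > best$score + tol)
      best <- list(score = s, position = off, strand = "+")
    roff <- n - L - off + 2        # revcomp offset whose forward position is off
    s <- score_window(pwm$log_odds, rev[roff:(roff + L - 1)])
    if (s > best$score + tol)
      best <- list(score = s, position = off, strand = "-")
  }
  best
}

#' Motif enrichment in elements versus background (hypergeometric)
#'
#' A sequence is a hit when its best scan score reaches `threshold` (default
#' 80% of the consensus score). Enrichment is the hypergeometric upper tail
#' of element hits among pooled element + background hits.
#'
#' @param element_seqs,background_seqs character vectors of DNA sequences.
#' @param pwm a `pwm` with log-odds.
#' @param threshold absolute score threshold; default `0.8 * consensus_score(pwm)`.
#' @param th thresholds (significance at `motif_enrich_p`).
#' @return One-row tibble: `tf`, `n_elements`, `n_background`, `hits_elements`,
#'   `hits_background`, `fraction`, `p`, `significant`.
#' @export
motif_enrichment <- function(element_seqs, background_seqs, pwm,
                             threshold = NULL, th = angio_thresholds()) {
  stopifnot(length(element_seqs) > 0, length(background_seqs) > 0)
  if (is.null(threshold)) threshold <- 0.8 * consensus_score(pwm)
  hit <- function(seqs) vapply(seqs, function(s)
    scan_best(pwm, s)$score >= threshold, logical(1), USE.NAMES = FALSE)
  he <- sum(hit(element_seqs)); hb <- sum(hit(background_seqs))
  ne <- length(element_seqs); nb <- length(background_seqs)
  K <- he + hb
  p <- if (he == 0) 1 else phyper(he - 1, K, ne + nb - K, ne,
                                  lower.tail = FALSE)
  tibble(tf = pwm$tf_name, n_elements = ne, n_background = nb,
         hits_elements = he, hits_background = hb, fraction = he / ne,
         p = p, significant = p < th$motif_enrich_p)
}

#' Allele-specific motif-disruption call for a SNP in an element
#'
#' Builds the reference and alternate sequence windows of `L - 1` flanking
#' bases around the SNP (truncated at the element edges and flagged `edge`),
#' scans both alleles, and calls a disruption when only hits covering the SNP
#' position are considered: `loss` when the reference window reaches the
#' threshold but the alternate does not, `gain` for the symmetric case.
#'
#' @param snp list/row with `snp_id`, `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases).
#' @param element one-row interval tibble containing the SNP.
#' @param genome named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param pwm a `pwm` with log-odds.
#' @param threshold hit threshold; default `0.8 * consensus_score(pwm)`.
#' @return One-row tibble (a circuit call): `snp_id`, `element_id`, `tf`,
#'   `ref_best`, `alt_best`, `delta`, `disrupted`, `direction`, `strand`,
#'   `offset`, `edge`.
#' @export
snp_disruption <- function(snp, element, genome, pwm, threshold = NULL) {
  stopifnot(!is.null(pwm$log_odds))
  if (is.null(threshold)) threshold <- 0.8 * consensus_score(pwm)
  L <- ncol(pwm$log_odds)
  pos0 <- snp$pos - 1L                       # 0-based SNP coordinate
  if (pos0 < element$start || pos0 >= element$end)
    abort("SNP not inside element")
  chrom_seq <- extract_chrom(genome, snp$chrom)
  win_start <- max(element$start, pos0 - (L - 1L))
  win_end <- min(element$end, pos0 + L)      # half-open
  edge <- (win_start > pos0 - (L - 1L)) || (win_end < pos0 + L)
  ref_seq <- toupper(substr(chrom_seq, win_start + 1L, win_end))
  snp_off <- pos0 - win_start + 1L           # 1-based within window
  if (substr(ref_seq, snp_off, snp_off) != toupper(snp$ref))
    warn(sprintf("%s: genome base %s differs from stated ref %s",
                 snp$snp_id, substr(ref_seq, snp_off, snp_off), snp$ref))
  # both windows carry the stated allele, so swapping ref/alt exactly
  # mirrors the call (flips delta, maps loss <-> gain)
  substr(ref_seq, snp_off, snp_off) <- toupper(snp$ref)
  alt_seq <- ref_seq
  substr(alt_seq, snp_off, snp_off) <- toupper(snp$alt)
  best_cov <- function(seq) best_hit_covering(pwm, seq, snp_off)
  rb <- best_cov(ref_seq); ab <- best_cov(alt_seq)
  loss <- rb$score >= threshold && ab$score < threshold
  gain <- ab$score >= threshold && rb$score < threshold
  tibble(snp_id = snp$snp_id,
         element_id = element$element_id %||% NA_character_,
         tf = pwm$tf_name, ref_best = rb$score, alt_best = ab$score,
         delta = rb$score - ab$score, disrupted = loss || gain,
         direction = if (loss) "loss" else if (gain) "gain" else "none",
         strand = rb$strand, offset = rb$position, edge = edge)
}

# best hit among windows whose footprint covers position `cover` (1-based)
best_hit_covering <- function(pwm, seq, cover) {
  L <- ncol(pwm$log_odds)
  n <- nchar(seq)
  if (n < L) return(list(score = -Inf, position = NA_integer_, strand = NA_character_))
  fwd <- strsplit(toupper(seq), "")[[1]]
  rev <- strsplit(revcomp(toupper(seq)), "")[[1]]
  best <- list(score = -Inf, position = NA_integer_, strand = NA_character_)
  tol <- 1e-9
  for (off in seq_len(n - L + 1)) {
    if (off > cover || off + L - 1 < cover) next
    s <- score_window(pwm$log_odds, fwd[off:(off + L - 1)])
    if (s > best$score + tol) best <- list(score = s, position = off, strand = "+")
    roff <- n - L - off + 2
    s <- score_window(pwm$log_odds, rev[roff:(roff + L - 1)])
    if (s > best$score + tol) best <- list(score = s, position = off, strand = "-")
  }
  best
}

extract_chrom <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) abort(paste0("chromosome missing: ", chrom))
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) abort(paste0("chromosome missing: ", chrom))
  genome[[chrom]]
}

#' Write PWMs in JASPAR text format
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(purrr::map(pwms, function(p) {
    c(paste0(">", p$tf_name, " ", p$tf_name),
      vapply(BASES, function(b)
        sprintf("%s  [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
        character(1)))
  }))
  readr::write_lines(lines, path)
  invisible(path)
}
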