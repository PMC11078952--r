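# Genomic interval algebra on plain tibbles.
#
# All coordinates are 0-based half-open (BED convention): an interval
# [start, end) covers bases start .. end-1. Adjacency at a shared boundary
# (end == next start) merges but does not count as overlap, matching
# bedtools merge/intersect defaults.

#' Construct / validate an interval tibble
#'
#' @param chrom chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (must exceed `start`).
#' @param name optional labels.
#' @param score optional numeric scores.
#' @param sorted sort by (chrom, start, end)? Default `TRUE`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` and, when supplied,
#'   `name` and `score`.
#' @examples
#' intervals("chr1", c(10, 5), c(20, 15))
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      sorted = TRUE) {
  x <- tibble(chrom = as.character(chrom),
              start = as.integer(start),
              end   = as.integer(end))
  if (!is.null(name))  x$name  <- as.character(name)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x)
  if (sorted) x <- arrange(x, .data$chrom, .data$start, .data$end)
  x
}

validate_intervals <- function(x, what = "interval set") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    abort(paste0(what, " needs columns chrom, start, end"))
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end))
    abort(paste0(what, ": non-integer coordinates"))
  if (any(x$start < 0)) abort(paste0(what, ": negative start"))
  if (any(x$end <= x$start)) abort(paste0(what, ": end <= start"))
  if (any(!nzchar(x$chrom))) abort(paste0(what, ": empty chromosome name"))
  invisible(x)
}

# Half-open tibble -> GRanges (1-based closed) and back.
as_granges <- function(x) {
  if (nrow(x) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_tbl <- function(gr) {
  if (length(gr) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer()))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end   = GenomicRanges::end(gr))
}

#' Read a BED file into an interval tibble
#'
#' Lines starting with `track`, `browser` or `#` are skipped. Coordinates are
#' kept 0-based half-open as stored in the file.
#'
#' @param path path to a tab-separated BED file.
#' @param min_fields minimum number of fields each data line must have
#'   (default 3). Fields 4 and 5, when present, populate `name` and `score`.
#'
#' @return A sorted interval tibble (possibly with 0 rows for an empty file).
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, min_fields = 3L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields))
    abort(sprintf("line %d: expected >= %d fields, got %d",
                  lineno[which(nf < min_fields)[1]], min_fields,
                  nf[which(nf < min_fields)[1]]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    abort(sprintf("line %d: non-integer coordinates", lineno[bad[1]]))
  bad <- which(end <= start)
  if (length(bad))
    abort(sprintf("line %d: end <= start", lineno[bad[1]]))
  nm <- if (max(nf) >= 4) vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", character(1)) else NULL
  sc <- if (max(nf) >= 5) {
    suppressWarnings(vapply(fields, function(f) if (length(f) >= 5) as.numeric(f[[5]]) else NA_real_, numeric(1)))
  } else NULL
  intervals(chrom, start, end, name = nm, score = sc)
}

#' Write an interval tibble as BED
#'
#' @param x interval tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x)) {
    cols <- c(cols, "name")
    if ("score" %in% names(x)) cols <- c(cols, "score")
  }
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}

#' Merge overlapping or nearby intervals
#'
#' Intervals on the same chromosome separated by at most `min_gap` bases are
#' fused. With the default `min_gap = 0` only touching or overlapping
#' intervals merge and the set of covered bases is preserved exactly.
#'
#' @param x interval tibble.
#' @param min_gap maximum gap (bp, >= 0) across which to merge.
#' @return A sorted interval tibble with no two intervals within `min_gap` bp
#'   on the same chromosome.
#' @examples
#' merge_intervals(intervals("chr1", c(5, 10), c(15, 20)))
#' @export
merge_intervals <- function(x, min_gap = 0L) {
  validate_intervals(x)
  stopifnot(min_gap >= 0)
  if (nrow(x) == 0) return(intervals(character(), integer(), integer()))
  red <- GenomicRanges::reduce(as_granges(x), min.gapwidth = min_gap + 1L)
  out <- granges_to_tbl(red)
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Flag query intervals overlapping a subject set
#'
#' @param query,subject interval tibbles.
#' @param min_overlap minimum shared bases (>= 1) for a hit. Half-open
#'   adjacency (query end == subject start) never counts.
#' @return Logical vector, one flag per row of `query` in input order.
#' @examples
#' overlaps_any(intervals("chr1", 0, 10), intervals("chr1", 9, 20))
#' @export
overlaps_any <- function(query, subject, min_overlap = 1L) {
  validate_intervals(query, "query")
  validate_intervals(subject, "subject")
  stopifnot(min_overlap >= 1)
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  # disjoint chromosome sets between query and subject are an ordinary
  # no-overlap situation, not worth a warning
  hits <- withCallingHandlers(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                                 minoverlap = min_overlap),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  hits > 0
}

#' Signed distance from each element to its nearest TSS
#'
#' The anchor is the element midpoint, `floor((start + end) / 2)`. Distance
#' is midpoint minus TSS position, minimised in absolute value over all TSSs
#' on the element's chromosome; ties go to the lexicographically smaller gene
#' id. Elements on chromosomes without any TSS get `NA` distance.
#'
#' @param elements interval tibble.
#' @param tss tibble with columns `chrom`, `pos` (TSS position, same
#'   coordinate system as midpoints), `gene_id`.
#' @return A tibble with one row per element (input order): `chrom`, `start`,
#'   `end`, `midpoint`, `tss_distance`, `nearest_gene`.
#' @export
nearest_tss_distance <- function(elements, tss) {
  validate_intervals(elements, "elements")
  stopifnot(all(c("chrom", "pos", "gene_id") %in% names(tss)))
  mid <- (elements$start + elements$end) %/% 2L
  out <- tibble(chrom = elements$chrom, start = elements$start,
                end = elements$end, midpoint = mid,
                tss_distance = NA_integer_, nearest_gene = NA_character_)
  if (nrow(elements) == 0 || nrow(tss) == 0) {
    if (nrow(elements) > 0)
      warn("elements on chromosome(s) without TSS: distance undefined")
    return(out)
  }
  for (ch in unique(elements$chrom)) {
    ei <- which(elements$chrom == ch)
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0) next
    # order TSS by (pos, gene_id) so equal-|distance| ties resolve to the
    # lexicographically smaller gene via the scan below
    tt <- tt[order(tt$pos, tt$gene_id), , drop = FALSE]
    pos <- tt$pos
    for (i in ei) {
      d <- mid[i] - pos
      ad <- abs(d)
      cand <- which(ad == min(ad))
      j <- cand[order(tt$gene_id[cand])[1]]
      out$tss_distance[i] <- d[j]
      out$nearest_gene[i] <- tt$gene_id[j]
    }
  }
  if (anyNA(out$tss_distance))
    warn(sprintf("%d element(s) on chromosome(s) without TSS: distance undefined",
                 sum(is.na(out$tss_distance))))
  out
}
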