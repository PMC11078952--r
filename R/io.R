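# File-format plumbing: minimal VCF, phenotype table, counts TSV, FASTA.

#' Write a genotype study as minimal VCF plus phenotype TSV
#'
#' Emits CHROM, POS, ID, REF, ALT, QUAL, FILTER, INFO, FORMAT and one GT
#' column per individual (0/0, 0/1, 1/1 or ./.), with the counted (minor)
#' allele as ALT.
#'
#' @param gs a [genotype_study()].
#' @param vcf_path,pheno_path output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_vcf <- function(gs, vcf_path, pheno_path = NULL) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- gs$genotypes
  header <- c("##fileformat=VCFv4.2",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     paste(gs$individuals$id, collapse = "\t")))
  body <- vapply(seq_len(nrow(gs$variants)), function(j) {
    v <- gs$variants[j, ]
    gt <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    paste(c(v$chrom, v$pos, v$snp_id, v$ref, v$alt, ".", "PASS", ".", "GT",
            gt), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, body), vcf_path)
  if (!is.null(pheno_path))
    readr::write_tsv(gs$individuals, pheno_path)
  invisible(list(vcf = vcf_path, pheno = pheno_path))
}

#' Read a minimal VCF plus phenotype TSV into a genotype study
#'
#' Only CHROM, POS, ID, REF, ALT and the GT subfield are used. Genotypes are
#' stored as ALT-allele counts.
#'
#' @param vcf_path path to the VCF.
#' @param pheno phenotype source: a path to a TSV with columns `id`,
#'   `phenotype`, or a tibble of the same shape.
#' @return A [genotype_study()].
#' @export
read_vcf <- function(vcf_path, pheno) {
  lines <- readr::read_lines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort("no #CHROM header line in VCF")
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  data <- lines[-seq_len(hdr)]
  data <- data[nzchar(data)]
  fields <- strsplit(data, "\t", fixed = TRUE)
  variants <- tibble(
    snp_id = vapply(fields, `[[`, character(1), 3),
    chrom = vapply(fields, `[[`, character(1), 1),
    pos = as.integer(vapply(fields, `[[`, character(1), 2)),
    ref = vapply(fields, `[[`, character(1), 4),
    alt = vapply(fields, `[[`, character(1), 5))
  parse_gt <- function(x) {
    gt <- sub(":.*", "", x)
    out <- rep(NA_integer_, length(gt))
    out[gt %in% c("0/0", "0|0")] <- 0L
    out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[gt %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- t(vapply(fields, function(f) parse_gt(f[-(1:9)]),
                   integer(length(ids))))
  geno <- t(geno)          # individuals x variants
  if (is.character(pheno)) pheno <- readr::read_tsv(pheno, show_col_types = FALSE)
  pheno <- pheno[match(ids, pheno$id), ]
  genotype_study(pheno, variants, geno)
}

#' Read a genes x samples counts TSV
#' @param path TSV path: first column gene ids, one column per sample.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_count_matrix(df)
}

#' Write a counts matrix as TSV
#' @param counts genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read a FASTA genome as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), sub("\\s.*", "", names(dss)))
}
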