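# Case-control exome-wide association: variant/individual QC, exact HWE,
# stratification PCA, per-SNP additive logistic regression, EM-based LD r^2,
# greedy clumping and LD expansion.

#' Assemble a genotype study
#'
#' @param individuals tibble with `id` and `phenotype` (`"case"`/`"control"`).
#' @param variants tibble with `snp_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param genotypes integer matrix, individuals x variants, values 0/1/2
#'   (minor-allele copies) or `NA` for missing.
#' @return Object of class `genotype_study`.
#' @export
genotype_study <- function(individuals, variants, genotypes) {
  stopifnot(all(c("id", "phenotype") %in% names(individuals)),
            all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  g <- as.matrix(genotypes)
  stopifnot(nrow(g) == nrow(individuals), ncol(g) == ncol(variants) ||
              ncol(g) == nrow(variants))
  if (ncol(g) != nrow(variants)) abort("genotype matrix dimension mismatch")
  if (anyNA(individuals$phenotype) ||
      !all(individuals$phenotype %in% c("case", "control")))
    abort("phenotype must be 'case' or 'control', non-missing")
  if (any(variants$pos <= 0)) abort("positions must be positive")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) abort("genotypes must be 0/1/2/NA")
  rownames(g) <- individuals$id
  colnames(g) <- variants$snp_id
  structure(list(individuals = as_tibble(individuals),
                 variants = as_tibble(variants), genotypes = g),
            class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("<genotype_study> %d individuals (%d cases / %d controls), %d variants\n",
              nrow(x$individuals), sum(x$individuals$phenotype == "case"),
              sum(x$individuals$phenotype == "control"), nrow(x$variants)))
  invisible(x)
}

is_sex_chrom <- function(chrom) {
  grepl("^(chr)?(X|Y)$", chrom, ignore.case = TRUE)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts
#' (plain two-sided p, not mid-p): p is the total probability of heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count.
#'
#' @param n_aa_major,n_het,n_aa_minor genotype counts (major homozygote,
#'   heterozygote, minor homozygote). Orientation does not matter.
#' @return p-value in (0, 1]; monomorphic samples give 1.
#' @examples
#' hwe_exact_p(25, 50, 25)
#' @export
hwe_exact_p <- function(n_aa_major, n_het, n_aa_minor) {
  stopifnot(n_aa_major >= 0, n_het >= 0, n_aa_minor >= 0)
  n <- n_aa_major + n_het + n_aa_minor
  if (n < 1) abort("empty sample")
  n_minor <- 2 * min(n_aa_major, n_aa_minor) + n_het
  if (min(n_aa_major, n_aa_minor) * 2 + n_het == 0 || n_minor == 0) return(1)
  dist <- hwe_het_distribution(n_minor, n)
  obs <- dist$prob[dist$het == n_het]
  if (!length(obs)) return(1)  # parity-inconsistent observation cannot occur
  sum(dist$prob[dist$prob <= obs * (1 + 1e-10)])
}

# Conditional distribution of the heterozygote count given n_minor minor
# alleles among 2n alleles: recurrence of the classic exact-test algorithm.
hwe_het_distribution <- function(n_minor, n) {
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  k <- length(hets)
  p <- numeric(k)
  # start from the largest heterozygote count and recur downward:
  # P(h-2)/P(h) = h(h-1) / (4 (hom_min + 1)(hom_maj + 1))
  p[k] <- 1
  if (k > 1) {
    for (i in (k - 1):1) {
      h <- hets[i + 1]
      hom_min <- (n_minor - h) / 2
      hom_maj <- (n_major - h) / 2
      p[i] <- p[i + 1] * h * (h - 1) / (4 * (hom_min + 1) * (hom_maj + 1))
    }
  }
  p <- p / sum(p)
  tibble(het = hets, prob = p)
}

#' Variant and individual quality control
#'
#' Individuals with genotyping rate < `call_rate_min` are removed first;
#' variants are then excluded if on a sex chromosome, call rate (over all
#' remaining individuals) < `call_rate_min`, minor allele frequency among
#' controls < `maf_min`, or control HWE exact p < `hwe_p_min`.
#'
#' @param gs a [genotype_study()].
#' @param th thresholds.
#' @return List: `study` (filtered [genotype_study()]), `variant_report`
#'   (per input variant: metrics, `pass`, `reason`), `individual_report`,
#'   `exclusions` (named counts per filter).
#' @export
variant_qc <- function(gs, th = angio_thresholds()) {
  ctrl0 <- gs$individuals$phenotype == "control"
  if (!any(ctrl0)) abort("no control individuals")
  g <- gs$genotypes
  ind_rate <- rowMeans(!is.na(g))
  ind_pass <- ind_rate >= th$call_rate_min
  g <- g[ind_pass, , drop = FALSE]
  ctrl <- gs$individuals$phenotype[ind_pass] == "control"

  call_rate <- colMeans(!is.na(g))
  gc <- g[ctrl, , drop = FALSE]
  n_called <- colSums(!is.na(gc))
  af <- colSums(gc, na.rm = TRUE) / (2 * pmax(n_called, 1))
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(gc)), function(j) {
    x <- gc[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  autosome <- !is_sex_chrom(gs$variants$chrom)

  reason <- rep(NA_character_, ncol(g))
  reason[call_rate < th$call_rate_min] <- "call rate"
  reason[maf < th$maf_min & is.na(reason)] <- "MAF"
  reason[hwe < th$hwe_p_min & is.na(reason)] <- "HWE"
  reason[!autosome] <- "sex chromosome"
  pass <- is.na(reason)

  vrep <- mutate(gs$variants, autosome = autosome, call_rate = call_rate,
                 maf_controls = maf, hwe_p_controls = hwe,
                 pass = pass, reason = reason)
  irep <- mutate(gs$individuals, genotyping_rate = ind_rate,
                 pass = ind_pass)
  if (!any(pass)) {
    tally <- table(reason)
    abort(paste0("all variants removed by QC: ",
                 paste(names(tally), tally, sep = "=", collapse = ", ")))
  }
  out <- genotype_study(gs$individuals[ind_pass, ],
                        gs$variants[pass, ],
                        g[, pass, drop = FALSE])
  excl <- c(individuals = sum(!ind_pass),
            `sex chromosome` = sum(reason == "sex chromosome", na.rm = TRUE),
            `call rate` = sum(reason == "call rate", na.rm = TRUE),
            MAF = sum(reason == "MAF", na.rm = TRUE),
            HWE = sum(reason == "HWE", na.rm = TRUE))
  list(study = out, variant_report = vrep, individual_report = irep,
       exclusions = excl)
}

#' Genotype PCA for population stratification
#'
#' Missing genotypes are mean-imputed; variant columns are centred and scaled
#' by `sqrt(2 p (1 - p))`; individuals are projected on the top two
#' components.
#'
#' @param gs a [genotype_study()].
#' @return `angio_pca` with per-individual coordinates (`sample` = id, plus
#'   `phenotype`) and explained-variance fractions.
#' @export
genotype_pca <- function(gs) {
  g <- gs$genotypes
  if (nrow(g) < 2 || ncol(g) < 2) abort("need >= 2 individuals and variants")
  p <- colMeans(g, na.rm = TRUE) / 2
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- 2 * p[j]
  keep <- p > 0 & p < 1 & apply(g, 2, sd) > 0
  g <- g[, keep, drop = FALSE]; p <- p[keep]
  z <- sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  coords <- tibble(sample = gs$individuals$id,
                   phenotype = gs$individuals$phenotype,
                   PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  structure(list(coords = coords, var_explained = ve), class = "angio_pca")
}

#' Per-SNP additive logistic association
#'
#' Fits logit P(case) = b0 + b1 * g per variant (g = minor-allele count;
#' missing genotypes dropped for that variant) by binomial IRLS, without
#' covariates, and reports the Wald test on b1. Monomorphic variants and
#' non-converged/separated fits get `converged = FALSE` and p = 1.
#'
#' @param gs a [genotype_study()].
#' @return Tibble (class `angio_assoc`): `snp_id`, `chrom`, `pos`, `n`,
#'   `beta`, `se`, `z`, `p`, `or`, `converged`.
#' @export
assoc_logistic_additive <- function(gs) {
  y_all <- as.integer(gs$individuals$phenotype == "case")
  if (length(unique(y_all)) < 2) abort("both phenotype classes required")
  g <- gs$genotypes
  fit_one <- function(j) {
    x <- g[, j]
    ok <- !is.na(x)
    xx <- x[ok]; yy <- y_all[ok]
    if (length(unique(xx)) < 2)
      return(c(NA, NA, NA, 1, 0, length(xx)))
    fit <- suppressWarnings(
      glm.fit(cbind(1, xx), yy, family = binomial(),
              control = list(epsilon = 1e-12, maxit = 100)))
    beta <- fit$coefficients[2]
    # observed-information covariance from the IRLS weights
    w <- fit$weights
    X <- cbind(1, xx)
    XtWX <- crossprod(X * sqrt(w))
    cv <- tryCatch(solve(XtWX), error = function(e) NULL)
    sep <- is.null(cv) || !fit$converged || abs(beta) > 15
    if (sep) return(c(beta, NA, NA, 1, 0, length(xx)))
    se <- sqrt(cv[2, 2])
    z <- beta / se
    c(beta, se, z, 2 * pnorm(-abs(z)), 1, length(xx))
  }
  res <- vapply(seq_len(ncol(g)), fit_one, numeric(6))
  out <- tibble(snp_id = gs$variants$snp_id, chrom = gs$variants$chrom,
                pos = gs$variants$pos, n = as.integer(res[6, ]),
                beta = res[1, ], se = res[2, ], z = res[3, ], p = res[4, ],
                or = exp(res[1, ]), converged = res[5, ] == 1)
  class(out) <- c("angio_assoc", class(out))
  out
}

#' Pairwise LD r-squared by EM haplotype estimation
#'
#' Estimates the four haplotype frequencies of two biallelic variants from
#' unphased genotypes with the standard EM over double-heterozygote phase
#' ambiguity, then returns r^2 = D^2 / (pA pa pB pb).
#'
#' @param g_a,g_b genotype vectors (0/1/2/NA) over the same individuals.
#' @param max_iter,tol EM controls.
#' @return r^2 in `[0, 1]`, or `NA` if either variant is monomorphic in the
#'   non-missing overlap or fewer than 5 individuals overlap.
#' @export
ld_r2 <- function(g_a, g_b, max_iter = 100L, tol = 1e-10) {
  ok <- !is.na(g_a) & !is.na(g_b)
  if (sum(ok) < 5) return(NA_real_)
  a <- g_a[ok]; b <- g_b[ok]
  pA <- mean(a) / 2; pB <- mean(b) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  n <- length(a)
  tab <- table(factor(a, 0:2), factor(b, 0:2))
  # haplotypes: 11, 10, 01, 00 (1 = minor allele); start from independence
  p11 <- pA * pB
  for (it in seq_len(max_iter)) {
    # only the double heterozygote (1,1) cell is phase-ambiguous
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    denom <- p11 * p00 + p10 * p01
    frac <- if (denom > 0) p11 * p00 / denom else 0.5
    # phase {11,00} contributes one 11-haplotype per double heterozygote
    n11 <- 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"] +
      frac * tab["1", "1"]
    new_p11 <- n11 / (2 * n)
    if (abs(new_p11 - p11) < tol) { p11 <- new_p11; break }
    p11 <- new_p11
  }
  D <- p11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

#' Lead-SNP extraction and LD expansion
#'
#' Exome-wide associated SNPs (p < `th$assoc_p`) are greedily clumped: the
#' best remaining p becomes a lead and all exome-wide SNPs with
#' r^2 >= `th$lead_r2` to it are dropped (ties on p break by lexicographic
#' `snp_id`). All QC-passing SNPs within `window` bp of a lead on the same
#' chromosome with r^2 > `th$expand_r2` are then collected as LD SNPs; the
#' associated set is the union of leads and LD SNPs.
#'
#' @param assoc result of [assoc_logistic_additive()].
#' @param gs the (QC-passing) [genotype_study()] used for `assoc`.
#' @param th thresholds.
#' @param window same-chromosome search window (bp) for r^2, default 1 Mb.
#' @return List of class `lead_expansion`: tibbles `exome_wide`, `leads`,
#'   `ld_snps`, `associated` (each with `snp_id`, `chrom`, `pos`, `p`; LD
#'   SNPs also carry `lead` and `r2`).
#' @export
extract_leads_and_expand <- function(assoc, gs, th = angio_thresholds(),
                                     window = 1e6) {
  geno <- gs$genotypes
  ew <- assoc[assoc$p < th$assoc_p & assoc$converged, ]
  ew <- arrange(ew, .data$p, .data$snp_id)
  if (nrow(ew) == 0) {
    warn("no exome-wide associated SNP")
    empty <- assoc[0, c("snp_id", "chrom", "pos", "p")]
    return(structure(list(exome_wide = empty, leads = empty,
                          ld_snps = mutate(empty, lead = character(0), r2 = numeric(0)),
                          associated = empty),
                     class = "lead_expansion"))
  }
  remaining <- ew
  leads <- ew[0, ]
  while (nrow(remaining) > 0) {
    lead <- remaining[1, ]
    leads <- bind_rows(leads, lead)
    if (nrow(remaining) == 1) break
    rest <- remaining[-1, ]
    r2 <- vapply(rest$snp_id, function(s) {
      if (rest$chrom[rest$snp_id == s][1] != lead$chrom) return(0)
      v <- ld_r2(geno[, lead$snp_id], geno[, s])
      if (is.na(v)) 0 else v
    }, numeric(1))
    remaining <- rest[r2 < th$lead_r2, ]
  }
  # expansion over all high-quality SNPs near any lead
  ld_list <- list()
  for (i in seq_len(nrow(leads))) {
    lead <- leads[i, ]
    cand <- gs$variants$chrom == lead$chrom &
      abs(gs$variants$pos - lead$pos) <= window &
      gs$variants$snp_id != lead$snp_id
    for (s in gs$variants$snp_id[cand]) {
      r2 <- ld_r2(geno[, lead$snp_id], geno[, s])
      if (!is.na(r2) && r2 > th$expand_r2)
        ld_list[[length(ld_list) + 1]] <- tibble(
          snp_id = s,
          chrom = gs$variants$chrom[gs$variants$snp_id == s],
          pos = gs$variants$pos[gs$variants$snp_id == s],
          p = assoc$p[match(s, assoc$snp_id)],
          lead = lead$snp_id, r2 = r2)
    }
  }
  ld_snps <- if (length(ld_list)) {
    distinct(bind_rows(ld_list), .data$snp_id, .keep_all = TRUE)
  } else {
    tibble(snp_id = character(), chrom = character(), pos = integer(),
           p = numeric(), lead = character(), r2 = numeric())
  }
  ld_snps <- ld_snps[!ld_snps$snp_id %in% leads$snp_id, ]
  keep_cols <- c("snp_id", "chrom", "pos", "p")
  associated <- distinct(bind_rows(leads[keep_cols], ld_snps[keep_cols]),
                         .data$snp_id, .keep_all = TRUE)
  structure(list(exome_wide = ew[keep_cols], leads = leads[keep_cols],
                 ld_snps = ld_snps, associated = associated),
            class = "lead_expansion")
}

#' @export
print.lead_expansion <- function(x, ...) {
  cat(sprintf("<lead_expansion> %d exome-wide, %d leads, %d LD SNPs, %d associated\n",
              nrow(x$exome_wide), nrow(x$leads), nrow(x$ld_snps),
              nrow(x$associated)))
  invisible(x)
}

#' Tidy an association result
#' @param x an `angio_assoc` tibble.
#' @param ... unused.
#' @return The per-SNP tibble (already tidy).
#' @method tidy angio_assoc
#' @export
tidy.angio_assoc <- function(x, ...) as_tibble(x)

#' One-row summary of an association scan
#' @param x an `angio_assoc` tibble.
#' @param ... unused.
#' @method glance angio_assoc
#' @export
glance.angio_assoc <- function(x, ...) {
  tibble(n_snps = nrow(x), n_converged = sum(x$converged),
         min_p = min(x$p), lambda_gc = stats::median(x$z^2, na.rm = TRUE) /
           stats::qchisq(0.5, 1))
}
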