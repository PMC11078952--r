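# Synthetic-data generator with planted ground truth. Emulates the study's
# inputs: a small genome with annotated genes, DNase/H3K27ac/H3K4me3 peak
# landscapes over a four-stage stimulation time course, NB counts with four
# planted temporal patterns, and a case-control genotype cohort with
# LD-block structure, planted QC violations and a planted risk SNP sitting
# inside a planted element where it disrupts a planted TF motif.

local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions: a 2 x 5 Mb genome with 100
#' genes; 30/20/10/15 enhancer-only / promoter-only / bifunctional / naked
#' planted open-chromatin loci plus 20 early-only decoy peaks; 800 genes
#' drawn from four temporal templates among 2000 stable genes (4 stages x 2
#' replicates); a 78-case / 100-control cohort (the published cohort sizes)
#' with 40 LD blocks of 10 SNPs, a planted causal variant of odds ratio
#' exp(1.3) at control MAF 0.30, and two planted violations of each variant
#' QC filter.
#'
#' @param seed master RNG seed; all generators derive their streams from it.
#' @param ... overrides of any default field.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
    n_genes = 100L, gene_length = 8000L,
    # peak landscape
    n_enhancer_only = 30L, n_promoter_only = 20L, n_bifunctional = 10L,
    n_naked = 15L, n_decoys = 20L,
    element_width = 400L, peak_jitter = 50L,
    # expression
    stages = c("H-0", "H-1", "H-4", "H-12"), n_rep = 2L,
    n_template_genes = 800L, n_null_genes = 2000L,
    base_mean = 300, template_amplitude = 1.5, nb_dispersion = 0.05,
    # genotypes
    n_cases = 78L, n_controls = 100L,
    n_blocks = 40L, block_size = 10L, n_haplotypes = 6L,
    snp_spacing = 1000L,
    causal_or = exp(1.3), causal_maf = 0.3,
    n_qc_low_call = 2L, n_qc_low_maf = 2L, n_qc_hwe = 2L, n_qc_sex = 2L,
    # planted motif
    motif_consensus = "ACGTGCAA", motif_tf = "SYNTF1",
    motif_strength = 85
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown sim_config field(s): ",
                                paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("sim_config", "list"))
}

# Deterministic gene layout: genes evenly spaced over the first 60% of each
# chromosome (the remaining 40% stays gene-free), alternating strands.
gene_layout <- function(cfg) {
  chroms <- names(cfg$chrom_sizes)
  per <- ceiling(cfg$n_genes / length(chroms))
  rows <- list()
  gi <- 0
  for (ch in chroms) {
    n_here <- min(per, cfg$n_genes - gi)
    if (n_here <= 0) break
    span <- 0.6 * cfg$chrom_sizes[[ch]]
    spacing <- floor(span / (n_here + 1))
    if (spacing <= cfg$gene_length + 2000)
      abort("infeasible packing: too many genes for chromosome size")
    for (i in seq_len(n_here)) {
      gi <- gi + 1
      start <- as.integer(i * spacing)
      end <- start + cfg$gene_length
      strand <- if (gi %% 2 == 1) "+" else "-"
      tss <- if (strand == "+") start else end
      rows[[gi]] <- tibble(gene_id = sprintf("GENE%04d", gi), chrom = ch,
                           strand = strand, tss = tss,
                           start = start, end = end)
    }
  }
  bind_rows(rows)
}

# Deterministic planted-element layout keyed to the gene grid. Classes:
# promoter-only near the TSS, bifunctional just upstream, enhancer-only and
# naked OCRs distal (20/40 kb), decoys further out. One locus per gene,
# cycling through genes, so loci never collide (gene spacing >> offsets).
element_plan <- function(cfg, genes) {
  classes <- c(rep("bifunctional", cfg$n_bifunctional),
               rep("promoter_only", cfg$n_promoter_only),
               rep("enhancer_only", cfg$n_enhancer_only),
               rep("naked", cfg$n_naked),
               rep("decoy", cfg$n_decoys))
  if (length(classes) > nrow(genes))
    abort("infeasible packing: more planted loci than genes")
  offset <- c(bifunctional = -1200L, promoter_only = -200L,
              enhancer_only = 20000L, naked = 40000L, decoy = 60000L)
  g <- genes[seq_along(classes), ]
  center <- g$tss + offset[classes]
  half <- cfg$element_width %/% 2L
  tibble(locus_id = sprintf("LOC%03d", seq_along(classes)),
         class = classes, chrom = g$chrom,
         start = as.integer(center - half), end = as.integer(center + half),
         anchor_gene = g$gene_id)
}

#' Simulate gene annotation and a genome sequence
#'
#' Genes are laid out non-overlapping with TSS, three exons and terminal
#' UTRs; base composition is i.i.d. uniform except at the planted motif
#' site: the planted TF's consensus is written into the centre of the
#' planted causal element (the first enhancer-only locus).
#'
#' @param cfg a [sim_config()].
#' @return List: `ann` ([gene_annotation()]), `genome` (named character
#'   vector of chromosome sequences), `motif` (`pwm` with log-odds),
#'   `causal_site` (tibble: locus, chrom, 1-based pos, ref, alt).
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  genes <- gene_layout(cfg)
  exon_rows <- purrr::pmap(genes, function(gene_id, chrom, strand, tss, start, end) {
    w <- 500L
    mid <- as.integer(start + (end - start) * 0.45)
    ex_start <- c(start, mid, end - w)
    ex_end <- c(start + w, mid + w, end)
    tibble(chrom = chrom, start = ex_start, end = ex_end, gene_id = gene_id)
  })
  exons <- bind_rows(exon_rows)
  utr5 <- mutate(genes,
                 s = if_else(.data$strand == "+", .data$start, .data$end - 100L),
                 e = if_else(.data$strand == "+", .data$start + 100L, .data$end))
  utr5 <- tibble(chrom = utr5$chrom, start = utr5$s, end = utr5$e,
                 gene_id = utr5$gene_id)
  utr3 <- mutate(genes,
                 s = if_else(.data$strand == "+", .data$end - 100L, .data$start),
                 e = if_else(.data$strand == "+", .data$end, .data$start + 100L))
  utr3 <- tibble(chrom = utr3$chrom, start = utr3$s, end = utr3$e,
                 gene_id = utr3$gene_id)
  ann <- gene_annotation(genes, exons = exons, utr5 = utr5, utr3 = utr3)

  genome <- local_seed(cfg$seed + 101L, {
    lapply(cfg$chrom_sizes, function(sz)
      paste(sample(BASES, sz, replace = TRUE), collapse = ""))
  })
  genome <- setNames(as.list(genome), names(cfg$chrom_sizes))
  genome <- lapply(genome, identity)
  genome <- unlist(genome)

  motif <- planted_motif(cfg)
  plan <- element_plan(cfg, genes)
  causal <- plan[plan$class == "enhancer_only", ][1, ]
  L <- nchar(cfg$motif_consensus)
  m_start <- (causal$start + causal$end) %/% 2L - L %/% 2L  # 0-based
  seqc <- genome[[causal$chrom]]
  substr(seqc, m_start + 1L, m_start + L) <- cfg$motif_consensus
  genome[[causal$chrom]] <- seqc
  # SNP at the motif's 4th column; alt chosen to flip to the weakest base
  snp_col <- 4L
  ref <- substr(cfg$motif_consensus, snp_col, snp_col)
  alt <- setdiff(BASES, ref)[1]
  causal_site <- tibble(locus_id = causal$locus_id, chrom = causal$chrom,
                        pos = m_start + snp_col,      # 1-based
                        ref = ref, alt = alt)
  list(ann = ann, genome = genome, motif = motif, causal_site = causal_site)
}

planted_motif <- function(cfg) {
  cons <- strsplit(cfg$motif_consensus, "")[[1]]
  L <- length(cons)
  counts <- matrix((100 - cfg$motif_strength) / 3, 4, L,
                   dimnames = list(BASES, NULL))
  for (j in seq_len(L)) counts[cons[j], j] <- cfg$motif_strength
  to_log_odds(structure(list(tf_name = cfg$motif_tf, counts = counts,
                             log_odds = NULL), class = "pwm"))
}

#' Simulate peak landscapes per timepoint
#'
#' Plants DNase peaks at every planted locus in the two late stages (with
#' boundary jitter), H3K27ac peaks over enhancer-only and bifunctional loci,
#' H3K4me3 peaks over promoter-only and bifunctional loci, and early-only
#' decoy DNase peaks that must never reach the element bank.
#'
#' @param cfg a [sim_config()].
#' @param ann result of [simulate_annotation()] (for the gene grid).
#' @return List: `dnase` (named list of interval tibbles per stage), `k27`,
#'   `k4` (named lists for the two late stages), `plan` (planted-locus truth
#'   table).
#' @export
simulate_peaks <- function(cfg = sim_config(), ann = NULL) {
  genes <- if (is.null(ann)) gene_layout(cfg) else ann$ann$genes
  plan <- element_plan(cfg, genes)
  late <- plan[plan$class != "decoy", ]
  decoy <- plan[plan$class == "decoy", ]
  j <- cfg$peak_jitter
  jit <- function(x, n) as.integer(x + sample(seq(-j, j), n, replace = TRUE))
  local_seed(cfg$seed + 202L, {
    mk <- function(rows) intervals(rows$chrom,
                                   pmax(0L, jit(rows$start, nrow(rows))),
                                   jit(rows$end, nrow(rows)),
                                   name = rows$locus_id)
    dnase <- list(
      `H-0` = mk(decoy), `H-1` = mk(decoy),
      `H-4` = mk(late), `H-12` = mk(late))
    enh <- late[late$class %in% c("enhancer_only", "bifunctional"), ]
    pro <- late[late$class %in% c("promoter_only", "bifunctional"), ]
    k27 <- list(`H-4` = mk(enh), `H-12` = mk(enh))
    k4 <- list(`H-4` = mk(pro), `H-12` = mk(pro))
    list(dnase = dnase, k27 = k27, k4 = k4, plan = plan)
  })
}

temporal_templates <- function() {
  rbind(down_convex  = c(1.8, 0.2, -0.8, -1.2),
        down_concave = c(1.2, 0.8, 0.2, -2.2),
        up_convex    = -c(1.8, 0.2, -0.8, -1.2),
        up_concave   = -c(1.2, 0.8, 0.2, -2.2))
}

#' Simulate a four-stage count matrix with planted temporal patterns
#'
#' Template genes follow one of four temporal shapes (two monotone-down, two
#' monotone-up across the time course, the reference cluster structure);
#' null genes are flat. Counts are negative binomial around the template
#' means; `nb_dispersion = 0` gives exactly the rounded means.
#'
#' @param cfg a [sim_config()].
#' @return List: `counts` (genes x samples integer matrix), `stages` (per
#'   sample), `truth` (tibble `gene_id`, `cluster` with 0 = null).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  tpl <- temporal_templates()
  k <- nrow(tpl)
  n_t <- cfg$n_template_genes; n_0 <- cfg$n_null_genes
  cluster <- c(rep(seq_len(k), length.out = n_t), rep(0L, n_0))
  n <- length(cluster)
  gene_id <- sprintf("SGENE%05d", seq_len(n))
  stages <- rep(cfg$stages, each = cfg$n_rep)
  local_seed(cfg$seed + 303L, {
    base <- exp(rnorm(n, log(cfg$base_mean), 0.4))
    lfc <- matrix(0, n, length(cfg$stages))
    is_t <- cluster > 0
    lfc[is_t, ] <- tpl[cluster[is_t], ] * cfg$template_amplitude
    mu <- base * 2^lfc
    counts <- matrix(0L, n, length(stages),
                     dimnames = list(gene_id,
                                     paste0(stages, "_r", rep(seq_len(cfg$n_rep),
                                                              length(cfg$stages)))))
    for (s in seq_along(stages)) {
      m <- mu[, match(stages[s], cfg$stages)]
      counts[, s] <- if (cfg$nb_dispersion == 0) as.integer(round(m))
                     else rnbinom(n, mu = m, size = 1 / cfg$nb_dispersion)
    }
    list(counts = counts, stages = stages,
         truth = tibble(gene_id = gene_id, cluster = cluster))
  })
}

#' Simulate a two-group count matrix with planted fold changes
#'
#' A focused differential-expression fixture: `n_de` genes at true
#' |log2FC| = `log2fc` (half up, half down) among `n_null` unchanged genes,
#' NB counts at the given mean and dispersion, `n_rep` replicates per group.
#'
#' @param n_null,n_de gene counts.
#' @param log2fc planted absolute log2 fold change.
#' @param base_mean,dispersion NB parameters.
#' @param n_rep replicates per group.
#' @param seed RNG seed.
#' @return List: `counts`, `stages` (`"A"`/`"B"`), `truth` (logical `de` per
#'   gene).
#' @export
simulate_de_counts <- function(n_null = 2000L, n_de = 100L, log2fc = 2,
                               base_mean = 500, dispersion = 0.05,
                               n_rep = 2L, seed = 1L) {
  n <- n_null + n_de
  sign <- c(rep(0, n_null), rep(c(1, -1), length.out = n_de))
  gene_id <- sprintf("DGENE%05d", seq_len(n))
  stages <- rep(c("A", "B"), each = n_rep)
  local_seed(seed + 404L, {
    mu_a <- rep(base_mean, n)
    mu_b <- base_mean * 2^(sign * log2fc)
    counts <- matrix(0L, n, length(stages),
                     dimnames = list(gene_id, paste0(stages, "_r",
                                                     rep(seq_len(n_rep), 2))))
    for (s in seq_along(stages)) {
      m <- if (stages[s] == "A") mu_a else mu_b
      counts[, s] <- rnbinom(n, mu = m, size = 1 / dispersion)
    }
    list(counts = counts, stages = stages,
         truth = tibble(gene_id = gene_id, de = sign != 0))
  })
}

#' Simulate a case-control genotype study with LD blocks
#'
#' Variants come in blocks; within a block each individual draws two
#' haplotypes from a small founder pool, which induces LD. One block carries
#' the planted causal SNP (located inside the planted element, inside the
#' planted motif footprint): case/control genotypes at that site follow an
#' additive logistic risk model with the configured odds ratio, and the
#' individual's two block haplotypes are drawn conditional on the causal
#' alleles. Planted QC violators (sex-chromosome, low call rate, low MAF,
#' HWE-violating variants) are appended, each violating exactly one filter.
#'
#' @param cfg a [sim_config()].
#' @param sim_ann result of [simulate_annotation()] (for the causal site).
#' @return List: `study` ([genotype_study()]), `truth` (list: `causal_snp`,
#'   `causal_block_snps`, `qc_plan` tibble of planted violators and the
#'   filter each must trip).
#' @export
simulate_genotypes <- function(cfg = sim_config(),
                               sim_ann = simulate_annotation(cfg)) {
  n_ind <- cfg$n_cases + cfg$n_controls
  phen <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  ind <- tibble(id = sprintf("IND%03d", seq_len(n_ind)), phenotype = phen)
  causal <- sim_ann$causal_site
  chroms <- names(cfg$chrom_sizes)

  local_seed(cfg$seed + 505L, {
    blocks <- vector("list", cfg$n_blocks)
    var_rows <- vector("list", cfg$n_blocks)
    causal_block <- 1L
    for (b in seq_len(cfg$n_blocks)) {
      K <- cfg$n_haplotypes
      m <- cfg$block_size
      # founder haplotypes and their frequencies; every block SNP is kept
      # comfortably polymorphic in the pool so only the planted violators
      # trip the QC filters
      hap <- matrix(rbinom(K * m, 1, 0.35), K, m)
      freq <- runif(K, 0.5, 1.5); freq <- freq / sum(freq)
      for (jj in seq_len(m)) {
        tries <- 0
        while ((f <- sum(freq[hap[, jj] == 1])) < 0.15 || f > 0.85) {
          hap[, jj] <- rbinom(K, 1, 0.35)
          if ((tries <- tries + 1) > 50) { hap[, jj] <- c(1, 1, rep(0, K - 2)); break }
        }
      }
      if (b == causal_block) {
        # column 1 is the causal site; set its allele so the pool frequency
        # of the risk allele is (close to) causal_maf
        ord <- order(freq)
        carry <- c()
        tot <- 0
        for (kk in ord) {
          if (tot + freq[kk] <= cfg$causal_maf + 0.02) {
            carry <- c(carry, kk); tot <- tot + freq[kk]
          }
        }
        if (!length(carry)) carry <- which.min(freq)
        hap[, 1] <- 0; hap[carry, 1] <- 1
        q <- sum(freq[carry])
        # per-individual causal genotype: HWE in controls, tilted by OR^g
        # in cases (retrospective sampling preserves the odds ratio)
        p0 <- c((1 - q)^2, 2 * q * (1 - q), q^2)
        p1 <- p0 * cfg$causal_or^(0:2); p1 <- p1 / sum(p1)
        gvec <- integer(n_ind)
        gvec[phen == "control"] <- sample(0:2, cfg$n_controls, TRUE, p0)
        gvec[phen == "case"] <- sample(0:2, cfg$n_cases, TRUE, p1)
        # draw the two block haplotypes conditional on the causal alleles
        pick <- function(allele) {
          pool <- which(hap[, 1] == allele)
          if (length(pool) == 1) pool else
            sample(pool, 1, prob = freq[pool])
        }
        h1 <- vapply(seq_len(n_ind), function(i)
          pick(as.integer(gvec[i] >= 1)), integer(1))
        h2 <- vapply(seq_len(n_ind), function(i)
          pick(as.integer(gvec[i] == 2)), integer(1))
      } else {
        h1 <- sample.int(K, n_ind, TRUE, freq)
        h2 <- sample.int(K, n_ind, TRUE, freq)
      }
      blocks[[b]] <- hap[h1, , drop = FALSE] + hap[h2, , drop = FALSE]
      ch <- chroms[(b - 1) %% length(chroms) + 1]
      if (b == causal_block) {
        ch <- causal$chrom
        pos <- causal$pos + (seq_len(m) - 1L) * cfg$snp_spacing
      } else {
        # non-causal blocks live in the gene-free tail of each chromosome,
        # away from the causal block's coordinates
        pos <- 3200000L + b * 30000L + (seq_len(m) - 1L) * cfg$snp_spacing
      }
      var_rows[[b]] <- tibble(
        snp_id = sprintf("rsB%02dS%02d", b, seq_len(m)),
        chrom = ch, pos = as.integer(pos),
        ref = "A", alt = "G", block = b)
    }
    geno <- do.call(cbind, blocks)
    variants <- bind_rows(var_rows)
    # the causal SNP gets its true identity, position and alleles
    variants$snp_id[1] <- "rsCAUSAL"
    variants$pos[1] <- causal$pos
    variants$ref[1] <- causal$ref
    variants$alt[1] <- causal$alt

    # planted QC violators
    qc_rows <- list(); qc_geno <- list(); reasons <- c()
    add <- function(snp_id, chrom, pos, g, reason) {
      qc_rows[[length(qc_rows) + 1]] <<- tibble(
        snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
        ref = "C", alt = "T", block = NA_integer_)
      qc_geno[[length(qc_geno) + 1]] <<- g
      reasons <<- c(reasons, reason)
    }
    clean_geno <- function(q) {
      g <- rbinom(n_ind, 1, q) + rbinom(n_ind, 1, q)
      g
    }
    for (i in seq_len(cfg$n_qc_sex))
      add(sprintf("rsSEX%02d", i), "chrX", 5000 + i * 1000,
          clean_geno(0.3), "sex chromosome")
    for (i in seq_len(cfg$n_qc_low_call)) {
      g <- clean_geno(0.3)
      g[sample.int(n_ind, ceiling(0.1 * n_ind))] <- NA
      add(sprintf("rsCALL%02d", i), chroms[1], 4e6 + i * 1000, g, "call rate")
    }
    for (i in seq_len(cfg$n_qc_low_maf))
      add(sprintf("rsMAF%02d", i), chroms[1], 4.1e6 + i * 1000,
          clean_geno(0.01), "MAF")
    for (i in seq_len(cfg$n_qc_hwe)) {
      # extreme heterozygote deficit at MAF ~ 0.5: alternate 0/2
      g <- rep(c(0L, 2L), length.out = n_ind)
      add(sprintf("rsHWE%02d", i), chroms[1], 4.2e6 + i * 1000, g, "HWE")
    }
    variants <- bind_rows(variants, bind_rows(qc_rows))
    geno <- cbind(geno, do.call(cbind, qc_geno))
    gs <- genotype_study(ind, variants[, c("snp_id", "chrom", "pos",
                                           "ref", "alt")], geno)
    truth <- list(
      causal_snp = "rsCAUSAL",
      causal_block_snps = c("rsCAUSAL",
                            sprintf("rsB01S%02d", 2:cfg$block_size)),
      qc_plan = tibble(snp_id = bind_rows(qc_rows)$snp_id, reason = reasons))
    list(study = gs, truth = truth)
  })
}

#' Random DNA sequences
#' @param n number of sequences.
#' @param len length of each.
#' @param seed RNG seed.
#' @param gc GC content (default 0.5).
#' @return Character vector of sequences.
#' @export
random_dna <- function(n, len, seed = 1L, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  local_seed(seed + 606L, {
    vapply(seq_len(n), function(i)
      paste(sample(BASES, len, TRUE, prob = p), collapse = ""), character(1))
  })
}
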