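# Independent oracles used across the test suite. Everything here is written
# from first principles (per-base masks, brute-force scans, closed-form
# enumeration, generic optimisers) so that package results can be checked
# against implementations that share no code with the package.

# ---- interval oracles -------------------------------------------------------

# per-base occupancy merge: mark covered bases (plus min_gap bridging) and
# read off maximal runs
oracle_merge <- function(x, min_gap = 0) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, ]
    hi <- max(xi$end)
    mask <- logical(hi + 1)
    for (i in seq_len(nrow(xi))) mask[(xi$start[i] + 1):xi$end[i]] <- TRUE
    # bridge gaps of length <= min_gap
    if (min_gap > 0) {
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$values)) {
        if (!r$values[j] && j > 1 && j < length(r$values) &&
            r$lengths[j] <= min_gap)
          mask[starts[j]:ends[j]] <- TRUE
      }
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (r$values[j])
        out[[length(out) + 1]] <-
          tibble::tibble(chrom = ch, start = starts[j] - 1L,
                         end = as.integer(ends[j]))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start, end)
}

# all-pairs overlap flags
oracle_overlaps <- function(query, subject, min_overlap = 1) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          pmin(subject$end, query$end[i]) -
          pmax(subject$start, query$start[i]) >= min_overlap)
  }, logical(1))
}

# brute-force nearest TSS with the documented tie-break
oracle_nearest <- function(elements, tss) {
  mid <- (elements$start + elements$end) %/% 2L
  dist <- rep(NA_integer_, nrow(elements))
  gene <- rep(NA_character_, nrow(elements))
  for (i in seq_len(nrow(elements))) {
    tt <- tss[tss$chrom == elements$chrom[i], ]
    if (nrow(tt) == 0) next
    d <- mid[i] - tt$pos
    best <- which(abs(d) == min(abs(d)))
    best <- best[order(tt$gene_id[best])][1]
    dist[i] <- d[best]
    gene[i] <- tt$gene_id[best]
  }
  list(midpoint = mid, tss_distance = dist, nearest_gene = gene)
}

# ---- statistics oracles -----------------------------------------------------

# direct BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# full-enumeration conditional HWE distribution via lchoose
oracle_hwe_dist <- function(n_minor, n) {
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(hom_min) - lfactorial(hom_maj) -
      lfactorial(h) + h * log(2) -
      (lfactorial(2 * n) - lfactorial(n_minor) - lfactorial(n_major))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  tibble::tibble(het = hets, prob = pr / sum(pr))
}

oracle_hwe_p <- function(n_hom_maj, n_het, n_hom_min) {
  n <- n_hom_maj + n_het + n_hom_min
  n_minor <- 2 * min(n_hom_maj, n_hom_min) + n_het
  if (n_minor == 0) return(1)
  d <- oracle_hwe_dist(n_minor, n)
  obs <- d$prob[d$het == n_het]
  if (!length(obs)) return(1)
  sum(d$prob[d$prob <= obs * (1 + 1e-10)])
}

# logistic regression by gradient BFGS on the exact log-likelihood
oracle_logistic <- function(g, y) {
  nll <- function(b) -sum(y * (b[1] + b[2] * g) - log1p(exp(b[1] + b[2] * g)))
  gr <- function(b) {
    p <- stats::plogis(b[1] + b[2] * g)
    c(-sum(y - p), -sum((y - p) * g))
  }
  stats::optim(c(0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))$par
}

# direct-ML LD r2: optimise the genotype likelihood over the 11-haplotype
# frequency (the only free parameter given the allele frequencies)
oracle_ld_r2_ml <- function(g_a, g_b) {
  pA <- mean(g_a) / 2; pB <- mean(g_b) / 2
  tab <- table(factor(g_a, 0:2), factor(g_b, 0:2))
  ll <- function(p11) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    if (min(p11, p10, p01, p00) < 0) return(-Inf)
    hp <- matrix(c(p00, p10, p01, p11), 2, 2)  # hp[a+1, b+1]
    s <- 0
    for (a in 0:2) for (b in 0:2) {
      nn <- tab[a + 1, b + 1]
      if (nn == 0) next
      pr <- if (a == 1 && b == 1) {
        2 * (p11 * p00 + p10 * p01)
      } else {
        ha <- switch(a + 1, c(0, 0), c(1, 0), c(1, 1))
        hb <- switch(b + 1, c(0, 0), c(1, 0), c(1, 1))
        tot <- hp[ha[1] + 1, hb[1] + 1] * hp[ha[2] + 1, hb[2] + 1] +
          hp[ha[1] + 1, hb[2] + 1] * hp[ha[2] + 1, hb[1] + 1]
        if (a == 1 || b == 1) tot else tot / 2
      }
      if (pr <= 0) return(-Inf)
      s <- s + nn * log(pr)
    }
    s
  }
  op <- stats::optimize(ll, c(max(0, pA + pB - 1), min(pA, pB)),
                        maximum = TRUE, tol = 1e-12)
  (op$maximum - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# ---- motif oracle -----------------------------------------------------------

oracle_revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# exhaustive scan over all offsets and both strands; ties keep the smallest
# forward offset, plus strand first (same documented convention and the same
# 1e-9 rounding tolerance)
oracle_scan <- function(pwm, seq) {
  lo <- pwm$log_odds
  L <- ncol(lo); n <- nchar(seq)
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(ch), function(j)
      if (ch[j] == "N") 0 else lo[ch[j], j], numeric(1)))
  }
  best <- NULL
  for (off in seq_len(n - L + 1)) {
    sub <- substr(seq, off, off + L - 1)
    for (st in c("+", "-")) {
      v <- score_one(if (st == "+") sub else oracle_revcomp(sub))
      if (is.null(best) || v > best$score + 1e-9)
        best <- list(position = off, strand = st, score = v)
    }
  }
  best
}

# ---- small constructors -----------------------------------------------------

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1000) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(50, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), start, start + len,
            sorted = FALSE)
}

make_study <- function(genotypes, n_cases, n_controls,
                       chrom = NULL, pos = NULL) {
  g <- as.matrix(genotypes)
  m <- ncol(g)
  ind <- tibble::tibble(id = sprintf("I%03d", seq_len(nrow(g))),
                        phenotype = c(rep("case", n_cases),
                                      rep("control", n_controls)))
  v <- tibble::tibble(
    snp_id = if (is.null(colnames(g))) sprintf("rs%03d", seq_len(m))
             else colnames(g),
    chrom = if (is.null(chrom)) rep("chr1", m) else chrom,
    pos = if (is.null(pos)) as.integer(seq_len(m) * 1000L) else as.integer(pos),
    ref = "A", alt = "G")
  genotype_study(ind, v, g)
}
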