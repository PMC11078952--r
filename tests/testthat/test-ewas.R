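# Genotype QC, HWE, association, LD and clumping.

test_that("hwe_het_distribution equals lchoose enumeration for all n <= 120", {
  for (n in c(1:40, seq(45, 120, by = 5))) {
    for (n_minor in 0:n) {   # n_minor up to n keeps minor allele the minor one
      if (n_minor == 0) next
      got <- hwe_het_distribution(n_minor, n)
      want <- oracle_hwe_dist(n_minor, n)
      expect_equal(got$het, want$het)
      expect_equal(got$prob, want$prob, tolerance = 1e-12)
    }
  }
})

test_that("hwe_exact_p equals the enumeration oracle on random counts up to N = 200", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(2:200, 1)
    g <- as.vector(rmultinom(1, n, c(0.45, 0.4, 0.15)))
    expect_equal(hwe_exact_p(g[1], g[2], g[3]),
                 oracle_hwe_p(g[1], g[2], g[3]), tolerance = 1e-12)
  }
  # orientation invariance and degenerate cases
  expect_equal(hwe_exact_p(10, 20, 5), hwe_exact_p(5, 20, 10))
  expect_equal(hwe_exact_p(50, 0, 0), 1)
  expect_error(hwe_exact_p(0, 0, 0), "empty")
})

test_that("simulated HWE type-I error sits in the binomial envelope of the enumerated size", {
  n <- 100; q <- 0.3; alpha <- 0.05
  # enumerate the exact size using only the oracle
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  size <- 0
  for (het in 0:n) for (hmin in 0:(n - het)) {
    hmaj <- n - het - hmin
    if (oracle_hwe_p(hmaj, het, hmin) < alpha)
      size <- size + exp(dmultinom(c(hmaj, het, hmin), prob = pg, log = TRUE))
  }
  expect_lte(size, alpha)          # the exact test is conservative
  nrep <- 10000
  set.seed(2024)
  rej <- 0
  for (i in seq_len(nrep)) {
    g <- sample(0:2, n, replace = TRUE, prob = pg)
    tab <- tabulate(g + 1L, 3L)
    if (hwe_exact_p(tab[1], tab[2], tab[3]) < alpha) rej <- rej + 1
  }
  half <- 1.96 * sqrt(size * (1 - size) / nrep)
  expect_gte(rej / nrep, size - half)
  expect_lte(rej / nrep, size + half)
})

test_that("variant_qc applies filters in order with sex chromosome overriding", {
  # 60 individuals: 10 cases, 50 controls. Enough good variants that one
  # missing genotype keeps an individual above the 0.95 genotyping rate,
  # and enough controls that an all-homozygote variant can reach HWE p < 1e-5.
  set.seed(13)
  n_good <- 20L
  good <- replicate(n_good, sample(0:2, 60, TRUE, prob = c(0.5, 0.35, 0.15)))
  colnames(good) <- sprintf("ok%d", seq_len(n_good))
  low_call <- good[, 1]; low_call[1:4] <- NA        # call rate 56/60 < 0.95
  low_maf <- c(sample(0:1, 10, TRUE), rep(0, 50))   # controls monomorphic
  hwe_bad <- c(sample(0:2, 10, TRUE), rep(c(0, 2), 25)) # controls all homozygote
  sexv <- good[, 2]
  g <- cbind(good, low_call = low_call, low_maf = low_maf,
             hwe_bad = hwe_bad, sexv = sexv)
  gs <- make_study(g, 10, 50,
                   chrom = c(rep("chr1", n_good + 3), "chrX"),
                   pos = seq_len(n_good + 4) * 100)
  qc <- variant_qc(gs)
  expect_true(all(qc$individual_report$pass))
  vr <- qc$variant_report
  expect_equal(vr$reason[match(c("low_call", "low_maf", "hwe_bad", "sexv"),
                               vr$snp_id)],
               c("call rate", "MAF", "HWE", "sex chromosome"))
  expect_true(all(vr$pass[vr$snp_id %in% sprintf("ok%d", seq_len(n_good))]))
  expect_equal(nrow(qc$study$variants), n_good)
  # HWE p for the planted violator is tiny among controls
  expect_lt(vr$hwe_p_controls[vr$snp_id == "hwe_bad"], 1e-5)
})

test_that("individuals failing genotyping rate are removed before variant filters", {
  set.seed(14)
  g <- replicate(6, sample(0:2, 20, TRUE, prob = c(0.45, 0.4, 0.15)))
  g[1, 1:2] <- NA                      # individual 1: rate 4/6 < 0.95
  gs <- make_study(g, 10, 10)
  qc <- variant_qc(gs)
  expect_equal(sum(!qc$individual_report$pass), 1L)
  expect_equal(nrow(qc$study$individuals), 19L)
  expect_equal(unname(qc$exclusions["individuals"]), 1L)
})

test_that("planted QC violators are flagged with exactly the planted reasons", {
  cfg <- sim_config(1)
  sg <- simulate_genotypes(cfg)
  qc <- variant_qc(sg$study)
  vr <- qc$variant_report
  ex <- vr[!vr$pass, ]
  plan <- sg$truth$qc_plan
  expect_setequal(ex$snp_id, plan$snp_id)
  expect_equal(ex$reason[match(plan$snp_id, ex$snp_id)], plan$reason)
})

test_that("additive logistic beta matches the likelihood-optimisation oracle to 1e-6", {
  set.seed(15)
  worst <- 0
  for (i in 1:50) {
    n <- sample(c(80, 120, 178), 1)
    q <- runif(1, 0.15, 0.45)
    g <- sample(0:2, n, TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    b0 <- rnorm(1, -0.2, 0.3); b1 <- rnorm(1, 0, 0.5)
    y <- rbinom(n, 1, plogis(b0 + b1 * g))
    if (length(unique(y)) < 2 || length(unique(g)) < 2) next
    n_case <- sum(y)
    o <- order(-y)
    gs <- make_study(matrix(g[o], ncol = 1), n_case, n - n_case)
    fit <- assoc_logistic_additive(gs)
    expect_true(fit$converged)
    want <- oracle_logistic(g, y)[2]
    worst <- max(worst, abs(fit$beta - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("null association p-values are uniform (chi-square GOF over 5000 null SNPs)", {
  set.seed(16)
  n <- 178
  g <- vapply(seq_len(5000), function(i) {
    q <- runif(1, 0.1, 0.5)
    sample(0:2, n, TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, numeric(n))
  gs <- make_study(g, 78, 100)
  fit <- assoc_logistic_additive(gs)
  ps <- fit$p[fit$converged]
  obs <- tabulate(pmin(floor(ps * 20) + 1L, 20L), 20L)
  expect_gt(chisq.test(obs)$p.value, 0.01)
  # and no inflation at the tail
  expect_lt(mean(ps < 0.01), 0.02)
})

test_that("separation and monomorphism are reported, not fabricated", {
  g_mono <- matrix(rep(1, 40), ncol = 1)
  g_sep <- matrix(c(rep(2, 20), rep(0, 20)), ncol = 1)
  gs <- make_study(cbind(mono = g_mono, sep = g_sep), 20, 20)
  fit <- assoc_logistic_additive(gs)
  expect_false(any(fit$converged))
  expect_equal(fit$p, c(1, 1))
})

test_that("EM r2 equals the closed form on known-phase fixtures (worked 0.36 case)", {
  # haplotype counts AB=40, Ab=10, aB=10, ab=40 paired homozygously:
  # no double heterozygotes, so haplotypes are directly countable
  g_a <- c(rep(2, 20), rep(2, 5), rep(0, 5), rep(0, 20))
  g_b <- c(rep(2, 20), rep(0, 5), rep(2, 5), rep(0, 20))
  expect_equal(ld_r2(g_a, g_b), 0.36, tolerance = 1e-9)
  # random known-phase fixtures
  set.seed(17)
  for (i in 1:40) {
    cnt <- as.vector(rmultinom(1, 60, c(0.35, 0.15, 0.15, 0.35))) + 1L
    ga <- c(rep(2, cnt[1]), rep(2, cnt[2]), rep(0, cnt[3]), rep(0, cnt[4]))
    gb <- c(rep(2, cnt[1]), rep(0, cnt[2]), rep(2, cnt[3]), rep(0, cnt[4]))
    nh <- 2 * sum(cnt)
    pA <- 2 * (cnt[1] + cnt[2]) / nh; pB <- 2 * (cnt[1] + cnt[3]) / nh
    D <- 2 * cnt[1] / nh - pA * pB
    want <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    expect_equal(ld_r2(ga, gb), want, tolerance = 1e-9)
  }
})

test_that("EM r2 equals direct likelihood maximisation on phase-ambiguous data", {
  set.seed(18)
  for (i in 1:40) {
    q1 <- runif(1, 0.2, 0.5); q2 <- runif(1, 0.2, 0.5)
    n <- 150
    h <- cbind(rbinom(2 * n, 1, q1), rbinom(2 * n, 1, q2))
    swap <- runif(2 * n) < 0.6
    h[swap, 2] <- h[swap, 1]
    g_a <- h[1:n, 1] + h[(n + 1):(2 * n), 1]
    g_b <- h[1:n, 2] + h[(n + 1):(2 * n), 2]
    r2 <- ld_r2(g_a, g_b)
    if (is.na(r2)) next
    expect_equal(r2, oracle_ld_r2_ml(g_a, g_b), tolerance = 1e-6)
  }
})

test_that("ld_r2 edge contracts: perfect LD, monomorphic, low overlap", {
  set.seed(19)
  g <- sample(0:2, 50, TRUE, prob = c(0.4, 0.4, 0.2))
  expect_equal(ld_r2(g, g), 1)
  expect_true(is.na(ld_r2(rep(0, 50), g)))
  g2 <- g; g2[1:46] <- NA
  expect_true(is.na(ld_r2(g2, g)))
})

test_that("two-locus fixture: exactly two leads and all planted proxies", {
  mk <- function(cc, kk) c(rep(2, cc[1]), rep(1, cc[2]), rep(0, cc[3]),
                           rep(2, kk[1]), rep(1, kk[2]), rep(0, kk[3]))
  L1 <- mk(c(40, 30, 8), c(10, 30, 60))
  P1 <- L1                              # perfect proxy, tie on p
  P2 <- L1; P2[1:28] <- 0               # sub-threshold proxy, r2 in (0.2, 0.6)
  N1 <- rep(c(0, 1, 2, 1), length.out = 178)
  L2 <- mk(c(38, 32, 8), c(12, 28, 60))
  P3 <- L2; P3[c(5:18, 85:100)] <- 1    # clumped proxy, r2 >= 0.6
  gs <- make_study(cbind(rsL1 = L1, rsP1 = P1, rsP2 = P2, rsN1 = N1,
                         rsL2 = L2, rsP3 = P3), 78, 100,
                   chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
                   pos = c(1000, 2000, 3000, 900000, 1000, 2000))
  le <- extract_leads_and_expand(assoc_logistic_additive(gs), gs)
  expect_equal(le$leads$snp_id, c("rsL1", "rsL2"))
  expect_setequal(le$ld_snps$snp_id, c("rsP1", "rsP2", "rsP3"))
  expect_equal(nrow(le$associated), 5L)
  # same-chromosome leads are pairwise r2 < 0.6
  g <- gs$genotypes
  for (i in seq_len(nrow(le$leads))) for (j in seq_len(nrow(le$leads))) {
    if (i >= j || le$leads$chrom[i] != le$leads$chrom[j]) next
    r2 <- ld_r2(g[, le$leads$snp_id[i]], g[, le$leads$snp_id[j]])
    expect_true(is.na(r2) || r2 < 0.6)
  }
})

test_that("lead extraction on the planted study recovers the causal block only", {
  cfg <- sim_config(1)
  sg <- simulate_genotypes(cfg)
  qc <- variant_qc(sg$study)
  fit <- assoc_logistic_additive(qc$study)
  expect_true(all(fit$converged))
  le <- extract_leads_and_expand(fit, qc$study)
  expect_equal(le$leads$snp_id, sg$truth$causal_snp)
  expect_true(all(le$associated$snp_id %in% sg$truth$causal_block_snps))
  expect_equal(nrow(le$associated),
               length(union(le$leads$snp_id, le$ld_snps$snp_id)))
})

test_that("no exome-wide SNP yields empty, warned result", {
  set.seed(20)
  g <- replicate(5, sample(0:2, 40, TRUE, prob = c(0.5, 0.4, 0.1)))
  gs <- make_study(g, 20, 20)
  fit <- assoc_logistic_additive(gs)
  expect_warning(le <- extract_leads_and_expand(fit, gs), "no exome-wide")
  expect_equal(nrow(le$leads), 0L)
  expect_equal(nrow(le$associated), 0L)
})

test_that("genotype_pca: homogeneous cohort shows no dominant axis; structured cohort does", {
  set.seed(21)
  g1 <- replicate(80, sample(0:2, 60, TRUE, prob = c(0.45, 0.4, 0.15)))
  gs1 <- make_study(g1, 30, 30)
  pc1 <- genotype_pca(gs1)
  expect_lt(pc1$var_explained[1], 0.1)
  # two diverged subpopulations separate on PC1
  qa <- rbeta(80, 0.4, 0.4)
  g2 <- rbind(
    t(replicate(30, rbinom(80, 2, qa))),
    t(replicate(30, rbinom(80, 2, 1 - qa))))
  gs2 <- make_study(g2, 30, 30)
  pc2 <- genotype_pca(gs2)
  grp <- rep(1:2, each = 30)
  expect_true(abs(cor(pc2$coords$PC1, grp)) > 0.9)
})

test_that("genotype_study validates inputs", {
  ind <- tibble::tibble(id = c("a", "b"), phenotype = c("case", "control"))
  v <- tibble::tibble(snp_id = "s", chrom = "chr1", pos = 10L,
                      ref = "A", alt = "G")
  expect_error(genotype_study(ind, v, matrix(3, 2, 1)), "0/1/2")
  ind2 <- ind; ind2$phenotype <- c("case", "unknown")
  expect_error(genotype_study(ind2, v, matrix(1, 2, 1)), "phenotype")
})

test_that("tidy and glance on association results", {
  cfg <- sim_config(1)
  sg <- simulate_genotypes(cfg)
  qc <- variant_qc(sg$study)
  fit <- assoc_logistic_additive(qc$study)
  expect_s3_class(tidy(fit), "tbl_df")
  gl <- glance(fit)
  expect_equal(gl$n_snps, nrow(qc$study$variants))
  expect_equal(gl$n_converged, sum(fit$converged))
  expect_equal(gl$min_p, min(fit$p))
})
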