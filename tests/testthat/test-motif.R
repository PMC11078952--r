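# PWM parsing, log-odds, scanning, enrichment and SNP disruption.

jaspar_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".jaspar",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

make_pwm <- function(consensus, strength = 85, tf = "TF1") {
  cons <- strsplit(consensus, "")[[1]]
  counts <- matrix((100 - strength) / 3, 4, length(cons),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- strength
  to_log_odds(structure(list(tf_name = tf, counts = counts, log_odds = NULL),
                        class = "pwm"))
}

test_that("read_jaspar parses records with scrambled row order and brackets", {
  path <- jaspar_file(c(
    ">MA0001.1 TFA",
    "G  [ 5 10 0 ]",
    "A  [ 80 0 20 ]",
    "T  [ 5 80 40 ]",
    "C  [ 10 10 40 ]",
    ">MA0002.1 TFB",
    "A 1 2",
    "C 3 4",
    "G 5 6",
    "T 7 8"))
  pwms <- read_jaspar(path)
  expect_length(pwms, 2L)
  expect_equal(pwms[[1]]$tf_name, "TFA")
  expect_equal(unname(pwms[[1]]$counts["A", ]), c(80, 0, 20))
  expect_equal(unname(pwms[[1]]$counts["G", ]), c(5, 10, 0))
  expect_equal(rownames(pwms[[1]]$counts), c("A", "C", "G", "T"))
  expect_equal(unname(pwms[[2]]$counts["T", ]), c(7, 8))
})

test_that("read_jaspar error contracts", {
  expect_error(read_jaspar(file.path(tempdir(), "nope.jaspar")), "no such file")
  expect_error(read_jaspar(jaspar_file(c("A 1 2", "C 1 2"))), "header")
  expect_error(read_jaspar(jaspar_file(c(">M X", "A 1", "C 1", "G 1"))),
               "4 matrix rows")
  expect_error(read_jaspar(jaspar_file(c(">M X", "A 1", "C 1", "G 1", "Z 1"))),
               "unlabelled")
  expect_error(read_jaspar(jaspar_file(
    c(">M X", "A 1 2", "C 1", "G 1 2", "T 1 2"))), "unequal")
  expect_error(read_jaspar(jaspar_file(
    c(">M X", "A 1 2", "C 1 2", "G 1 2", "T 1 q"))), "non-numeric")
  expect_error(read_jaspar(jaspar_file(
    c(">M X", "A -1 2", "C 1 2", "G 1 2", "T 1 2"))), "negative")
  expect_error(read_jaspar(jaspar_file(
    c(">M X", "A 0 2", "C 0 2", "G 0 2", "T 0 2"))), "zero column")
  expect_error(read_jaspar(jaspar_file(
    c(">M X", "A 1 2", "A 1 2", "G 1 2", "T 1 2"))), "one row per base")
})

test_that("to_log_odds matches the pseudocount formula exactly", {
  counts <- matrix(c(100, 0, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- to_log_odds(structure(list(tf_name = "X", counts = counts,
                                  log_odds = NULL), class = "pwm"))
  # log2(((100 + 1 * 0.25) / (100 + 1)) / 0.25)
  expect_equal(unname(p$log_odds["A", 1]), log2((100.25 / 101) / 0.25))
  expect_equal(unname(p$log_odds["A", 1]), 1.98926, tolerance = 1e-5)
  expect_equal(unname(p$log_odds["C", 1]), log2((0.25 / 101) / 0.25))
  # a uniform column is exactly zero log-odds for every base
  u <- matrix(25, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  pu <- to_log_odds(structure(list(tf_name = "U", counts = u,
                                   log_odds = NULL), class = "pwm"))
  expect_equal(unname(pu$log_odds[, 1]), rep(0, 4))
  # background validation
  expect_error(to_log_odds(p, background = c(0.5, 0.5, 0.25, -0.25)))
  expect_error(to_log_odds(p, background = c(0.3, 0.3, 0.3, 0.3)))
  expect_error(to_log_odds(p, pseudocount = 0))
})

test_that("consensus_score is the attainable maximum and is attained", {
  pwm <- make_pwm("ACGTGCAA")
  cs <- consensus_score(pwm)
  expect_equal(cs, sum(apply(pwm$log_odds, 2, max)))
  hit <- scan_best(pwm, "ACGTGCAA")
  expect_equal(hit$score, cs)
  expect_equal(hit$position, 1L)
  expect_equal(hit$strand, "+")
  set.seed(31)
  for (s in random_dna(20, 60, seed = 31))
    expect_lte(scan_best(pwm, s)$score, cs + 1e-12)
})

test_that("scan_best equals the exhaustive oracle on random sequences and motifs", {
  set.seed(32)
  mismatch <- 0L
  for (i in 1:60) {
    cons <- paste(sample(c("A", "C", "G", "T"), sample(5:10, 1), TRUE),
                  collapse = "")
    pwm <- make_pwm(cons, strength = sample(c(55, 70, 85), 1))
    seq <- random_dna(1, sample(30:120, 1), seed = 32000 + i)
    got <- scan_best(pwm, seq)
    want <- oracle_scan(pwm, seq)
    if (!isTRUE(all.equal(got$score, want$score, tolerance = 1e-9)) ||
        got$position != want$position || got$strand != want$strand)
      mismatch <- mismatch + 1L
  }
  expect_equal(mismatch, 0L)
})

test_that("scanning is strand-symmetric in score and errors on short input", {
  pwm <- make_pwm("ACGTGC")
  set.seed(33)
  for (s in random_dna(20, 40, seed = 33)) {
    expect_equal(scan_best(pwm, s)$score,
                 scan_best(pwm, oracle_revcomp(s))$score, tolerance = 1e-12)
  }
  # a planted forward hit is found on the minus strand of the reverse complement
  s <- paste0(random_dna(1, 15, seed = 34), "ACGTGC", random_dna(1, 15, seed = 35))
  expect_equal(scan_best(pwm, s)$strand, "+")
  expect_equal(scan_best(pwm, oracle_revcomp(s))$strand, "-")
  expect_error(scan_best(pwm, "ACG"), "shorter than motif")
  # N bases contribute zero
  expect_equal(scan_best(pwm, "NNNNNN")$score, 0)
})

test_that("hypergeometric enrichment: planted motif in half the elements", {
  pwm <- make_pwm("ACGTGCAA")
  bg <- random_dna(2000, 200, seed = 41)
  el <- random_dna(200, 200, seed = 42)
  plant <- seq_len(100)
  el[plant] <- vapply(el[plant], function(s) {
    substr(s, 97, 104) <- "ACGTGCAA"; s
  }, character(1), USE.NAMES = FALSE)
  res <- motif_enrichment(el, bg, pwm)
  expect_lt(res$p, 1e-20)
  expect_true(res$significant)
  expect_gte(res$hits_elements, 100L)
  expect_gte(res$fraction, 0.5)
  # oracle identity: hypergeometric upper tail on the realised hit counts
  K <- res$hits_elements + res$hits_background
  expect_equal(res$p, phyper(res$hits_elements - 1, K,
                             res$n_elements + res$n_background - K,
                             res$n_elements, lower.tail = FALSE))
})

test_that("enrichment null and degenerate cases", {
  pwm <- make_pwm("ACGTGCAA")
  el <- random_dna(100, 200, seed = 43)
  bg <- random_dna(1000, 200, seed = 44)
  res <- motif_enrichment(el, bg, pwm)
  expect_false(res$significant)
  # zero element hits -> p = 1 by convention
  short_el <- random_dna(20, 12, seed = 45)    # hits ~impossible at 0.8 consensus
  res0 <- motif_enrichment(short_el, bg, pwm)
  if (res0$hits_elements == 0) expect_equal(res0$p, 1)
  expect_error(motif_enrichment(character(0), bg, pwm))
})

test_that("snp_disruption calls a designed loss and mirrors under allele swap", {
  pwm <- make_pwm("ACGTGCAA")
  flank_l <- random_dna(1, 96, seed = 51)
  flank_r <- random_dna(1, 96, seed = 52)
  chrom_seq <- paste0(flank_l, "ACGTGCAA", flank_r)   # motif at 1-based 97..104
  genome <- c(chrX = chrom_seq)
  element <- intervals("chrX", 0L, nchar(chrom_seq))
  element$element_id <- "E1"
  snp <- list(snp_id = "rs1", chrom = "chrX", pos = 100L, ref = "T", alt = "C")
  call <- snp_disruption(snp, element[1, ], genome, pwm)
  expect_true(call$disrupted)
  expect_equal(call$direction, "loss")
  expect_gt(call$delta, 0)
  expect_false(call$edge)
  # swapping ref and alt flips the call exactly
  snp2 <- list(snp_id = "rs1b", chrom = "chrX", pos = 100L, ref = "C", alt = "T")
  expect_warning(call2 <- snp_disruption(snp2, element[1, ], genome, pwm),
                 "differs from stated ref")
  expect_equal(call2$direction, "gain")
  expect_equal(call2$delta, -call$delta)
  expect_equal(call2$ref_best, call$alt_best)
  expect_equal(call2$alt_best, call$ref_best)
})

test_that("snp_disruption: covering-hit restriction, edge flag, and errors", {
  pwm <- make_pwm("ACGTGCAA")
  # element truncates the scan window around a SNP near its edge
  chrom_seq <- paste0("ACGTGCAA", random_dna(1, 92, seed = 53))
  genome <- c(chr9 = chrom_seq)
  el <- intervals("chr9", 0L, 100L)
  el$element_id <- "E2"
  snp_edge <- list(snp_id = "rsE", chrom = "chr9", pos = 4L,
                   ref = "T", alt = "G")
  call <- snp_disruption(snp_edge, el[1, ], genome, pwm)
  expect_true(call$edge)
  expect_equal(call$direction, "loss")
  # a SNP far from any motif instance is not a disruption
  snp_far <- list(snp_id = "rsF", chrom = "chr9", pos = 60L,
                  ref = substr(chrom_seq, 60, 60), alt = "A")
  if (snp_far$alt == snp_far$ref) snp_far$alt <- "C"
  far <- snp_disruption(snp_far, el[1, ], genome, pwm)
  expect_false(far$disrupted)
  expect_equal(far$direction, "none")
  # the reported hit covers the SNP: window is pos0 - 7 .. pos0 + 8, so the
  # SNP sits at in-window offset 8 and any covering hit starts at 1..8
  expect_true(far$offset >= 1 && far$offset <= 8)
  expect_error(
    snp_disruption(list(snp_id = "rsO", chrom = "chr9", pos = 150L,
                        ref = "A", alt = "C"), el[1, ], genome, pwm),
    "not inside element")
  expect_error(
    snp_disruption(snp_far, el[1, ], c(chr1 = "ACGT"), pwm),
    "chromosome missing")
})

test_that("the planted causal SNP disrupts the planted TF motif", {
  sim <- simulate_annotation(sim_config(1))
  site <- sim$causal_site
  plan_el <- intervals(site$chrom, site$pos - 201L, site$pos + 199L)
  plan_el$element_id <- site$locus_id
  snp <- list(snp_id = "rsCAUSAL", chrom = site$chrom, pos = site$pos,
              ref = site$ref, alt = site$alt)
  call <- snp_disruption(snp, plan_el[1, ], sim$genome, sim$motif)
  expect_true(call$disrupted)
  expect_equal(call$direction, "loss")
})

test_that("write_jaspar round-trips counts through read_jaspar", {
  pwm1 <- make_pwm("ACGTGC", tf = "RT1")
  pwm2 <- make_pwm("TTAACC", strength = 70, tf = "RT2")
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(list(pwm1, pwm2), path)
  back <- read_jaspar(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$tf_name, "RT1")
  expect_equal(back[[1]]$counts, pwm1$counts, ignore_attr = TRUE)
  expect_equal(back[[2]]$counts, pwm2$counts, ignore_attr = TRUE)
})
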