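Package: angiocre
Title: Angiogenic Cis-Regulatory Elements and Cis-Regulatory SNP Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a bank of angiogenic cis-regulatory elements from
    open-chromatin (DNase-seq) and histone-mark (H3K27ac, H3K4me3) peak
    sets, characterises temporal transcriptome dynamics by differential
    expression and fuzzy c-means time-series clustering, and identifies
    disease-associated cis-regulatory SNPs via case-control association,
    LD clumping and expansion, element intersection, and allele-specific
    motif-disruption scoring. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
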