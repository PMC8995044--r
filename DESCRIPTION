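Package: gbmti
Title: Gene Body Methylation and Transcript Integrity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links gene body methylation (gbM) status to transcript
    integrity in plant genomes. Classifies genes as gbM, unmethylated (UM)
    or TE-like methylated (teM) from per-cytosine bisulfite counts using
    exact binomial tests against the genic-average methylation rate;
    classifies full-length long-read (Isoseq-style) alignments for
    conventional versus internal transcription start, antisense
    orientation and intron retention; computes short-read exon3/exon1
    coverage ratios and intron RPKM; and compares gbM versus UM gene
    groups with Wilcoxon rank-sum tests and covariate-adjusted binomial
    regression. A seeded synthetic-data generator with planted gene
    classes and effect sizes makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
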