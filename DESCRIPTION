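Package: rohscan
Title: Runs-of-Homozygosity Detection and ROH-Island Analysis for SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the analysis of runs of homozygosity (ROH) in
    SNP-array genotypes of livestock populations. Reads PLINK text PED/MAP
    files; applies per-sample and per-SNP call-rate filters and an exact
    Hardy-Weinberg equilibrium test; calibrates the minimum SNP count per run
    from the genome-wide false-positive formula; detects ROH with the
    consecutive-SNP scanning method under heterozygote and missing-call
    allowances; calls ROH islands from per-SNP population support; summarizes
    ROH lengths by Mb class and per-chromosome coverage; annotates islands
    against a BED gene track; and scans a continuous phenotype against
    per-locus ROH state by linear regression with Bonferroni control. A
    seeded synthetic-population generator with planted autozygous segments
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
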