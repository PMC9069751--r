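Package: bulkpop
Title: Bulked-Sample SNP Analysis for Open-Pollinated Variety Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Population-genetic analysis of pooled ("bulked") DNA samples of
    open-pollinated plant varieties genotyped as diploid SNP calls. Reads and
    screens multi-sample VCFs of biallelic SNPs, computes per-variety
    diversity indices (Ne, Na, Ho, He, Nei's gene diversity, Shannon index,
    nucleotide diversity), partitions variance by distance-based AMOVA with
    permutation tests for overall and pairwise PhiST, sizes minimal SNP
    marker panels by bootstrap subsampling, and summarises relatedness via
    VanRaden genomic kinship, bootstrapped neighbor-joining trees, principal
    components and the Evanno delta-K statistic. Includes a calibrated
    synthetic-data generator emulating the multi-variety bulked sampling
    design so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
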