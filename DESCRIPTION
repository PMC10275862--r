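Package: radmut
Title: Mutational Profiles of Particle-Irradiated Clonal Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutational profiles of clonally
    expanded human cell lines exposed to particle radiation (proton and
    helium-ion beams). Reads jointly genotyped multi-sample VCFs and applies
    the clone-attribution filter cascades for SNVs, small indels and
    structural variants; classifies mutations into 6-class and SBS96
    trinucleotide spectra, the ID83 indel scheme and SV classes; extracts de
    novo mutational signatures by Kullback-Leibler non-negative matrix
    factorization with bootstrap stability assessment, and assigns or
    decomposes them against reference catalogs; detects clustered point
    mutations (omikli- and kataegis-like) via the 1 kb cluster-graph rule;
    compares burdens and signature exposures between treatment groups with a
    label-shuffling randomization test using empirical p-values and
    Benjamini-Hochberg correction; models regional mutation-rate enrichment
    across replication-timing or expression bins with negative binomial
    regression; and simulates synthetic clone cohorts with known truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
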