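Package: dropphase
Title: Chromosomal Phasing of Variant Pairs from Droplet Digital PCR
    Co-Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines the chromosomal phase (cis or trans) of pairs of
    sequence variants from droplet digital PCR (ddPCR) co-partitioning
    data. Physically linked alleles co-segregate into the same nanoliter
    droplets, so the excess of double-positive droplets over the chance
    expectation reveals phase. The package estimates free and linked
    molecule rates from the four droplet classes by Poisson-partition
    statistics, computes percent linkage with chi-square significance and
    bootstrap confidence intervals, classifies two-channel droplet
    amplitudes into the four droplet classes even when allele probes
    cross-react, calls diplotypes from redundant quad-duplex designs,
    fits an exponential fragment-survival model of percent linkage versus
    genomic distance, and simulates complete experiments (fragmentation,
    partitioning, fluorescence) with ground truth attached.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
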