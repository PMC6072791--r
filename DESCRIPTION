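Package: plasmatrack
Title: Tumor-Informed and Biopsy-Free Detection of Circulating Tumor DNA
    from Targeted Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection and longitudinal monitoring of circulating
    tumor DNA (ctDNA) from targeted deep sequencing of cell-free plasma DNA.
    Implements a tumor-informed plasma tracking test (per-site background
    allele-frequency percentile plus a binomial error test), a biopsy-free
    somatic SNV caller over strand-split Q30 allele counts (binomial test
    against matched germline, z-test against a cross-plasma background panel,
    Bonferroni correction, supporting-read, strand-bias, proximity-window,
    lane-SNP and consequence filters), per-site background error models,
    tumor-burden summaries with one-way ANOVA and Fisher's LSD post-hoc
    tests, exact binomial confidence intervals for concordance,
    limit-of-detection arithmetic from unique depth and input DNA mass, and a
    seeded synthetic cohort generator (matched germline, tumor and plasma
    trios, reference-standard dilution series, technical replicate pairs) so
    the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
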