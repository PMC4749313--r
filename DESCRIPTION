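Package: cnvdiet
Title: Diet-Driven Copy-Number Evolution Analyses for Dog Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of diet-driven gene copy-number evolution across dog
    breeds: robust nonparametric comparisons of droplet-digital-PCR diploid
    copy-number calls between diet groups (Fligner-Policello robust rank
    order and Fligner-Killeen variance tests, implemented from first
    principles with an exact permutation oracle), an array-CGH
    regression-residual outlier statistic for a focal gene against a
    cross-breed null distribution of copy-number-variable sites, a
    latitude-based starch-intake proxy analysis, and a derived-allele-
    frequency-difference (dDAF) ancestry-informative-SNP introgression scan
    between dogs and wolves. Includes seeded synthetic-data generators that
    emulate every input (ddPCR copy-number tables, aCGH log2-ratio site
    tables, biallelic genotype panels with configurable wolf introgression)
    so each stage is verifiable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
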