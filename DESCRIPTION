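Package: rarecase
Title: Family-Based Genomic Case Analysis of Rare Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the family-based (trio plus tumor) genomic workup of a
    rare solid tumor: classification of exome variants into somatic, de novo,
    rare-homozygous and compound-heterozygous classes under explicit depth,
    allele-fraction and population-frequency thresholds; copy-number
    segmentation of probe-level log2 ratios with cross-platform concordance
    scoring against read-depth calls; interchromosomal translocation breakpoint
    delimitation from discordant mate-pairs with junction assay design; and
    Poisson quantification of droplet digital PCR assays for circulating
    tumor DNA monitoring. Includes a synthetic-data generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
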