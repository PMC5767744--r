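Package: polyAT
Title: Associative Transcriptomics for Allopolyploid Crop Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Association mapping from transcriptome functional genotypes in
    allopolyploid crops such as oilseed rape. Calls and classifies polyploid
    SNPs (simple and hemi-SNPs arising from homoeologue cross-mapping) from
    per-accession pileup summaries, quantifies transcript abundance as RPKM,
    estimates population structure (admixture Q matrix), kinship and linkage
    disequilibrium, runs mixed-linear-model SNP association and fixed-effect
    gene-expression-marker (GEM) regression with genomic control, and
    validates top markers by take-one-out trait prediction. Includes a
    synthetic allopolyploid diversity-panel simulator so every stage is
    testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
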