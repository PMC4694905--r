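Package: famvarscan
Title: Familial Rare-Variant Segregation, Expression Association and
    Survival Cutoff Scanning for Neuroblastoma Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pedigree-aware pipeline for discovering rare predisposition
    variants in familial cancer. Implements kinship and expected
    identity-by-descent sharing on arbitrary pedigrees, gene-dropping
    simulation, a multi-stage exome variant filtering cascade (shared by
    affected, absent in unaffected, rarity by minor allele frequency,
    consequence class) with segregation and penetrance analysis,
    CDS-to-protein coding-effect annotation with HGVS-style naming on
    either strand, qPCR reference-gene stability (geNorm M) and calibrated
    relative quantification with association tests against MYCN status,
    and Kaplan-Meier optimal-cutpoint log-rank scanning of expression for
    overall survival. A synthetic-cohort generator emits every input
    format the pipeline reads, so all stages are testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
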