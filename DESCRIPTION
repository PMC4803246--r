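Package: vdrescan
Title: Vitamin D Response Element Scanning and Regulatory Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Position-weight-matrix discovery of vitamin D response elements
    (DR3-type RXR/VDR sites) in gene regulatory regions, rescoring of mutant
    alleles to quantify how promoter and intronic variants disturb or duplicate
    binding sites, cohort allele-frequency and dominant-model genotype-phenotype
    association statistics for anticoagulant activity traits, and qPCR
    dose-response quantification by the comparative CT method. Includes seeded
    synthetic-data generators (planted motifs, Hardy-Weinberg cohorts, qPCR
    plates) so every stage is testable without external downloads, and a
    pipeline that orchestrates the full analysis into a structured report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
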