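Package: lipidpanel
Title: Targeted-Panel Genetic Characterization of Dyslipidemias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for hybrid targeted sequencing panels used in
    dyslipidemia genetics: rare-variant prioritization through a staged
    filter cascade (allele frequency, protein-altering consequence, in-silico
    deleteriousness), read-depth copy-number variant calling against a
    reference panel of CNV-free samples, small weighted polygenic scores for
    LDL cholesterol, triglyceride and HDL cholesterol with percentile-based
    extreme-score classification, and per-patient genetic profiles and
    clinical-style reports that combine rare-variant and polygenic findings.
    Includes a synthetic cohort generator with known ground truth so every
    stage can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
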