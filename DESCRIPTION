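Package: hapanel
Title: Targeted Gene-Panel Interpretation for Pulmonary Arterial Hypertension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interpretation toolkit for a 21-gene pulmonary arterial hypertension
    (PAH) capture panel (HAP v1.2): sample-level sequencing quality control
    (coverage at 20x, capture uniformity, Ti/Tv ratios), offline snapshot-based
    variant annotation, a staged variant prioritization cascade, an ACMG/AMP
    evidence-combination engine producing the five-tier classification,
    cross-sample read-depth CNV calling on capture targets, digenic and
    biallelic (compound-heterozygous) inheritance detection against pedigrees,
    and cohort-level reporting. Ships a curated worked-example case set
    (digenic families, ABCC8 carriers, associated-PAH forms, biallelic EIF2AK4
    PVOD cases) mapped onto a packaged toy transcript model, and a synthetic
    cohort generator with planted truth so every pipeline stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
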