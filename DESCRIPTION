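Package: FamVarPrior
Title: Pedigree-Based Germline Variant Prioritization for Familial Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes rare germline variants in cancer-prone families from
    joint-genotyped whole-genome calls. Implements call-quality, strand-bias,
    population-frequency and dominant-model segregation filtering against a
    pedigree; a coding arm combining CADD and conservation thresholds with
    consensus deleteriousness voting across missense and nonsense effect
    predictors and intolerance-based ranking; a non-coding arm intersecting
    UTR and gene-flank variants with miRNA target, promoter, enhancer,
    super-enhancer and transcription-factor binding site tracks; screening of
    candidates against cancer predisposition gene panels; rare structural
    variant filtering; tiered per-family candidate reports; and a synthetic
    cohort simulator with a planted dominant causal variant for end-to-end
    validation without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
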