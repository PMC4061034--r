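Package: famvar
Title: Family-Based Exome Variant Filtering and Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the family-based exome filtering
    strategy used to nominate rare dominant candidate variants in small
    disease pedigrees: per-sample variant quality control, capture-target
    restriction, consequence-based exclusion of non-protein-disrupting
    variants, an ordered population-database allele-frequency exclusion
    cascade, dominant-model shared-variant filtering across affected and
    unaffected exomes, co-segregation checking in extended relatives, a
    transparent predictor-consensus ranking, and case-control allelic
    association tests.  Includes a seeded synthetic pedigree-exome generator
    producing complete input bundles (VCF, PED, BED, annotation and panel
    tables) with a planted causal variant, so every stage is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
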