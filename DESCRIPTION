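Package: uvsig
Title: UV-Induced Mutational Signature Analysis for Mouse Melanoma Exomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-variant-calling analysis of UV-exposed mouse melanoma
    exomes: ensemble consensus of somatic call sets, dipyrimidine event
    collapsing, SBS96 trinucleotide mutation spectra, transcriptional
    strand-bias testing, de novo mutational-signature extraction by
    non-negative matrix factorization with bootstrap stability-based rank
    selection, signature-catalog matching with permutation p-values,
    copy-number burden summaries, group and survival statistics, and
    erythemal (McKinlay-Diffey) UV dosimetry. Includes a seeded synthetic
    data generator that plants known signatures, strand bias, dinucleotide
    events, copy-number fractions and survival parameters so that every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    pracma,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SomaticMutation, VariantAnnotation, Software, StatisticalMethod
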