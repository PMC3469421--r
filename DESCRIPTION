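Package: decayQTL
Title: RNA Decay Rate Estimation and Decay-QTL Mapping from
    Transcription-Arrest Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates relative mRNA decay rates from actinomycin-D
    transcription-arrest time courses measured across many individuals,
    relates inter-individual decay variation to steady-state expression
    levels, and maps cis-acting RNA decay QTLs (rdQTLs) and expression
    QTLs with permutation-based false discovery rate control, Storey pi0
    estimation with bootstrap lambda selection, and closed-form overlap
    arithmetic between QTL classes. Ships a synthetic study generator
    with planted genetic effects on decay and transcription for power
    and calibration analyses, emulating an equal-mass hybridization
    design in which measured decay rates are relative to the mean
    cellular decay rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, GeneRegulation, SNP, GenomeWideAssociation,
    TimeCourse, Transcriptomics
RoxygenNote: 7.3.3
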