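Package: codonSDA
Title: Supply-to-Demand Adaptation of the tRNA Pool from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tRNA isoacceptors from small RNA-seq alignments and
    scores codon optimality as the balance between anticodon supply and
    expression-weighted codon demand. Builds mature tRNA reference libraries
    (intron removal, CCA addition, identical-sequence clustering) together
    with the pre-tRNA and masked-genome artifacts used for two-pass read
    filtering; computes relative codon usage, tRNA adaptation index weights
    under wobble pairing rules, relative tAI, codon demand, and per-codon
    Supply-to-Demand Adaptation weights (SDAw) with per-gene scores; calls
    candidate tRNA modification sites from base misincorporation in uniquely
    mapped reads and projects them onto a consensus tRNA structural model;
    and provides the cohort-level statistics used to compare conditions:
    Wilcoxon differential tests with FDR control, promoter-methylation and
    copy-number feature extraction over tRNA genes, per-isoacceptor multiple
    linear regression with coefficient-sign binomial tests, and Kaplan-Meier
    survival stratification by SDAw. Includes seeded generators for every
    input so the full pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    survival,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
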