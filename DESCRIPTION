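Package: subtypeqtl
Title: Transcriptome-Defined Subtypes and Interacting QTL in Half-Sib Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting a complex trait in a single-sire half-sib
    family by combining expression profiling with QTL interval mapping.
    Provides factor-adjusted transcript-trait association (a latent-factor
    model fitted by EM that removes hidden expression heterogeneity
    independent of the trait), hierarchical clustering of animals into
    molecular subtypes, paternal transmission-probability computation by a
    hidden Markov model under the Haldane map function, approximate
    likelihood-ratio interval mapping with empirical chromosome-wide
    thresholds and one-LOD support intervals, leave-one-subtype-out scans,
    paternal haplotype calling at QTL regions, QTL-by-QTL interaction tests
    (two-way ANOVA on haplotype classes and fixed-locus interaction scans),
    and a candidate-gene filter for transcripts whose expression maps to two
    interacting loci. A synthetic-data generator emulating the half-sib
    design with two interacting fatness QTL and factor-structured hepatic
    expression makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
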