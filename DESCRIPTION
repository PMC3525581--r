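Package: sdesr
Title: Sex-Dimorphic Expression Scoring and Pathway Enrichment for
    Toxicogenomic Time Courses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies genes that respond to chemical exposure in opposite
    directions in male and female animals. Converts replicated two-colour
    microarray log-ratios into per-condition Z-normalised signed significance
    scores, computes a silhouette-based Sex-Dependent Expression Score (SDES)
    per gene and time point, clusters condition profiles with rank-correlation
    distances, runs a permutation-based gene set enrichment analysis on the
    SDES-ranked lists, and assembles an annotated metabolic pathway cross-talk
    network. Ships a synthetic-data generator that emulates a four-chemical,
    two-sex, four-time-point toxicogenomic study design with planted
    sex-dimorphic structure, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
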