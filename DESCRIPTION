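Package: regenet
Title: Dynamic Gene Co-Expression Network Analysis of Heart Regeneration Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for dynamic gene co-expression network
    analysis of injury/regeneration expression time courses, modelled on the
    zebrafish cardiac cryoinjury design (control plus 4 hpi to 90 dpi in
    triplicate). Provides empirical-Bayes moderated differential expression
    with probe collapsing and Benjamini-Hochberg control, soft-threshold
    weighted co-expression networks (a_ij = |r_ij|^beta) with scale-free and
    density/heterogeneity diagnostics, module detection by topological-overlap
    hierarchical clustering and by cohesiveness-based overlapping clustering,
    permutation tests on weighted connectivity for hub identification,
    hypergeometric functional enrichment, cross-species conservation tests and
    miR-target intersection against local tables, plus a synthetic time-course
    generator with planted modules, hubs and injury-responsive genes so that
    every stage is verifiable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
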