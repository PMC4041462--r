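Package: vdjoin
Title: Annotation, Simulation and Cohort Statistics for V(D)J
    Recombination Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decomposes V(D)J recombination coding and signal joints into
    retained germline sequence, deletions, P and N nucleotides,
    microhomology and miscleavage, and classifies signal joints as precise
    or imprecise (including an in-silico ApaL1 check).  Detects adjacent
    direct repeats (ADRs) at junctions and scores them against a
    per-locus insertion-probability null model.  Scans arbitrary DNA for
    cryptic recombination signal sequences (cRSSs), scoring 12/23-paired
    candidates by consensus match counts.  Aggregates per-junction
    annotations into cohort summary tables with the associated
    contingency-table statistics, and simulates junction cohorts with
    ground truth under classical and alternative end-joining regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
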