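Package: tfchrono
Title: Time-Resolved Analysis of Pioneer Transcription-Factor-Driven
    Chromatin and Expression Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-course analysis of transcription-factor-driven
    lineage programming. Classifies TF binding sites by temporal occupancy
    (persistent versus transient, stratified by gain time), builds
    RPKM-normalized signal matrices and accessibility clusters around binding
    sites, quantifies CpG demethylation dynamics at low-methylated regions,
    calls Tn5-protection footprints with a strand-aware binomial score and
    maps motif occupancy and pairwise co-occurrence over time, clusters
    differential-expression trajectories against model profiles, and
    classifies secondary-factor binding sites by their dependence on a
    pioneer factor. Includes a synthetic multi-omic time-course generator
    with planted ground truth so the whole pipeline is testable end to end
    at toy-genome scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
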