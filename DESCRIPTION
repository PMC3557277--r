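Package: slrpipe
Title: Replicate-Consistency Filtering and Consensus Clustering of
    Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicated microarray time courses of
    surgically induced osteoarthritis (destabilization of the medial
    meniscus) and matched sham controls. Builds signal-log-ratio (SLR)
    time courses against averaged baselines, applies a four-stage
    replicate-consistency filter (detection p-value, SLR magnitude,
    replicate overlap, and Pearson-correlation/Euclidean-distance
    consistency with a 2-of-3 rule), selects the cluster number by a
    leave-one-timepoint-out figure of merit, and resolves stable
    expression clusters by threshold-resolved consensus k-means over
    replicate datasets. Includes a synthetic-data generator that emulates
    the study design (pooled replicates, four timepoints, one missing
    pool) with planted truth labels for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
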