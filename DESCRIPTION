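Package: sedapipe
Title: Authentication and Taxonomic Profiling of Sedimentary Ancient DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a sedimentary ancient DNA
    (sedaDNA) authentication and taxonomic-profiling workflow for deep
    marine sediment cores: chemical-tracer contamination QC with
    blank-based detection limits, read filtering (length, low-complexity,
    deduplication), k-mer seeded semiglobal alignment of shotgun reads
    against merged marker-gene references with naive lowest-common-ancestor
    assignment, subtraction of control-derived contaminants, terminal
    C-to-T deamination damage authentication with decay-model fitting, and
    relative-abundance, rarefaction and correlation statistics. A
    ground-truthed synthetic sediment-core generator emulates down-core
    libraries with age-graded damage, a dated taxon-composition step
    change, modern contaminants shared with controls, tracer measurement
    runs and correlated geochemistry, so the whole pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
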