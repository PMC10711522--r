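Package: motuforge
Title: DNA Barcode Reference Libraries, Barcode Gaps and MOTU Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating DNA barcode reference
    libraries of the kind assembled for regional fish faunas. Computes
    pairwise Kimura 2-parameter distances with pairwise deletion,
    per-species barcode-gap records (maximum intraspecific versus
    nearest-neighbour distance), and rank-level divergence summaries;
    delimits molecular operational taxonomic units (MOTUs) with four
    algorithms (threshold single-linkage clustering, hierarchical
    distance partitioning with gap-width and panmixia scoring, the
    Poisson tree process on metric trees, and the general mixed
    Yule-coalescent threshold model on ultrametric trees); combines
    delimitations by majority-rule consensus and reports splits and
    lumps against morphological species; and draws sequence
    accumulation curves. A coalescent-within-Yule K80 sequence
    simulator with known truth supports end-to-end validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    cluster,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
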