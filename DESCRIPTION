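Package: varconcord
Title: Multi-Laboratory Variant Sharing, Quality Control and Classification Concordance
Version: 0.1.0
Authors@R: person("varconcord", "maintainers", email = "maintainers@varconcord.org", role = c("aut", "cre"))
Description: Backend toolkit for a multi-laboratory hereditary-cancer variant
    sharing database. Ingests per-laboratory classification and individual
    metadata tables through per-lab format mappings with automatic
    pseudo-anonymization, applies record-level VCF hard filters and
    cohort-level sample tests (noisy, empty, duplicate, kinship),
    normalizes indels to left and right representations against a reference
    sequence, computes coverage-aware kinship-deduplicated allele
    frequencies stratifiable by any metadata field, maintains a
    latest-per-laboratory five-tier classification ledger with tiered
    concordance models, and plans a three-phase discrepancy-resolution
    strategy with revision accounting. A deterministic fixture generator
    produces every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    igraph,
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
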