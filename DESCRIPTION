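Package: mutatlas
Title: Pan-Cancer Analysis of Somatic Mutations in miRNA Biogenesis Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a pan-cancer atlas of somatic mutations in
    microRNA (miRNA) biogenesis genes and tracing their downstream effects on
    miRNA expression. Reads somatic variant calls from four caller dialects,
    applies read-support and quality reliability filters, merges calls across
    callers without duplication and restricts them to extended coding regions;
    computes hypermutation exclusion, mutation-class summaries, mutation
    density, per-gene per-cancer overmutation enrichment and recurrently
    mutated amino-acid hotspots; performs mutation-group differential miRNA
    analysis with per-cancer range normalization, re-normalization against a
    DICER1-independent reference miRNA (miR-451a), and 5p/3p arm-asymmetry
    statistics; quantifies isomiR 5'-end heterogeneity; and associates
    mutation groups with survival, tumor stage and copy-number status. A
    fully synthetic cohort generator with planted effects provides ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
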