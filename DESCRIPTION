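Package: selandscape
Title: Super-Enhancer Landscapes and Differential H3K27ac Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of H3K27ac ChIP-seq landscapes
    under drug treatment: replicate-consensus peak construction, ROSE-style
    super-enhancer stitching with TSS exclusion, cluster quantification and
    fixed-threshold super-enhancer calling, negative-binomial differential
    occupancy testing with a three-tier mark classification, multi-condition
    direction-pattern grouping, proximal-gene annotation, hypergeometric
    gene-set enrichment, expression response clustering, and rank-based
    comparison of survival-associated gene sets. Includes a synthetic-data
    generator with planted truth so every stage can be validated end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
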