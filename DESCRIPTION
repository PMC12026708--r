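Package: tempodeg
Title: Temporal Pattern Classification of Differential Expression After
    Diffuse Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-timepoint bulk RNA-seq studies of
    traumatic brain injury: count filtering and median-of-ratios
    normalization, negative-binomial Wald differential expression, a six-way
    temporal pattern classifier (Early, Transient, Persistent, Intensified,
    Delayed, Late), cell-type specificity scoring with the tau index,
    dampened/accelerated treatment-effect calling, gene-set
    overrepresentation with Fisher's exact test, and a signed weighted
    co-expression network workflow (biweight midcorrelation, topological
    overlap, module eigengenes). Includes a negative-binomial count
    simulator that plants temporal patterns, treatment effects,
    cell-type-specific genes, and correlated modules with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
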