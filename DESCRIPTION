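Package: comod
Title: Weighted Gene Co-Expression Modules and Trait Association for Islet Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from log2 expression
    matrices (absolute-correlation similarity, soft-threshold adjacency chosen
    by the scale-free topology criterion, topological overlap), detects
    co-expression modules by average-linkage clustering of the topological
    overlap dissimilarity with eigengene-based membership refinement, and
    associates module eigengenes with clinical traits by covariate-adjusted
    linear and logistic regression. Includes gene-set overlap enrichment with
    Fisher's exact test and Benjamini-Hochberg correction, hub (intramodular
    connectivity) analyses, cross-dataset differential-expression signature
    concordance, resampling-based region enrichment, and a four-condition
    causal inference test for dose - mediator - outcome triplets. A synthetic
    cohort generator with planted modules, labelled hub gene sets and planted
    trait effects makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
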