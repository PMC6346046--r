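Package: pcdevnet
Title: Temporal Co-Expression Modules and Comorbidity-Stratified
    Odds-Ratio Permutation Tests for Developing Neuronal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for developmental time-course RNA-seq of a
    purified neuronal population: median-of-ratios normalization and RPKM,
    sample-level quality control (principal-component separation of time
    points, marker-panel verification), signed weighted co-expression
    network analysis with topological overlap, module eigengenes and
    module membership, a negative-binomial likelihood-ratio time-course
    test, gene-length-bias-corrected over-representation via the Wallenius
    noncentral hypergeometric distribution, and a cross-tissue
    ratio-of-odds-ratios permutation test with Patefield margin-conditional
    table sampling and Haldane correction, stratified by intellectual
    disability co-morbidity. Includes a synthetic-data generator with
    known ground truth emulating a five-time-point, three-replicate
    design with planted monotone temporal modules and planted disease-list
    composition biases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
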