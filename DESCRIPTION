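Package: epidiff
Title: Integrative Differential Transcriptome and Epigenome Analysis for
    Paired Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for comparing a cancer-derived and a normal-derived
    cell line across matched RNA-seq and ChIP-seq data: RPKM
    quantification with TMM normalization and Fisher exact differential
    expression, window/gap ChIP-seq island calling against input DNA with
    differential-island testing, expression-quartile TSS metagene
    profiles, copy-number-aware mapping-bias controls, length-bias-aware
    category enrichment via the Wallenius noncentral hypergeometric
    distribution, 3-criterion candidate-gene prioritization, and ddCt
    qPCR validation statistics. Includes a synthetic-data module that
    generates complete toy studies with planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
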