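Package: selix
Title: Genomic Selection Indices for Simultaneous Improvement of Grain
    Yield and Protein Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying simultaneous genomic selection for grain
    yield and protein content in inbred line breeding programmes.
    Implements a two-stage phenotypic analysis (per-trial best linear
    unbiased estimates with repeatability-based trial filtering and an
    across-trial combination model), marker quality control, a genomic
    relationship matrix, GBLUP with homogeneous or stage-specific
    (heterogeneous) residual variances, grain protein/yield deviations
    and the corresponding phenotypic and genomic restriction indices,
    and a replicated forward-prediction harness that measures prediction
    accuracy and predicted response to selection.  A synthetic
    breeding-programme generator provides multi-year populations with a
    configurable negative genetic correlation between yield and protein
    content, so that every stage of the pipeline can be exercised and
    tested without proprietary breeding data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
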