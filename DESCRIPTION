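Package: circarenal
Title: Circadian Rhythm Analysis of Dual-Platform Renal Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and compares circadian rhythms in kidney transcriptomes
    profiled on mixed microarray and RNA-seq platforms. Implements the full
    preprocessing cascade (intensity and count filtering, log2 transformation
    with global-median normalization, per-platform median centering,
    common-gene merging, quantile normalization, and parametric
    empirical-Bayes batch correction), per-gene rhythm detection by one-way
    ANOVA screening followed by a rank-based umbrella (rise-then-fall) test
    with exact or permutation p-values, single-component cosinor rhythmometry
    (MESOR, amplitude, acrophase) for physiological time series,
    remission-correction scoring of diurnally regulated genes, and
    blood-pressure dipper-status classification. A synthetic-data generator
    with exported ground truth emulates the dual-platform circadian study
    design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    optparse,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
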