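Package: coexmod
Title: Weighted Gene Co-Expression Modules and Driver-Anchored Candidate
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from bulk
    transcriptomic expression matrices using biweight midcorrelation,
    soft-threshold adjacency and topological overlap, detects co-expression
    modules with a dynamic hybrid tree cut and eigengene merging, quantifies
    module robustness across tree-cut hyperparameters, tests permutation-based
    module preservation across datasets and differential co-expression across
    paired conditions, scores samples with rank-based hub-gene signatures, and
    prioritizes candidate genes anchored on a driver gene of interest. Includes
    a factor-model synthetic-data generator with planted modules, a planted
    driver gene and a planted candidate hub gene so that every stage of the
    analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
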