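Package: circafly
Title: Circadian, Photic and Survival Phenotyping of Drosophila Disease Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis stack for behavioral and molecular phenotyping of
    tissue-restricted Drosophila disease models. Parses Trikinetics DAM
    beam-break monitor files, quantifies circadian locomotor rhythmicity by
    the autocorrelation rhythm index with period estimation and actogram /
    profile construction, scores acute startle responses to light
    transitions and day/night activity partitioning, detrends and
    cosinor-fits bioluminescence reporter traces, compares cohort survival
    curves with a generalized Wilcoxon test, and runs factor-adjusted
    differential expression with empirical-interval signature overlap
    against reference fold-change tables. A synthetic-data module generates
    every input class with machine-readable ground truth so all stages are
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    survival,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
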