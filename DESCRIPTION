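Package: proxbias
Title: Observer-Proximity Bias in Animal Social Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how observer proximity interacts with
    individual tolerance phenotypes to bias inter-individual association
    patterns and social networks measured by focal sampling of habituated
    animal groups. Provides a mechanistic simulator of observer-induced
    displacement with known ground truth, mixed-model estimation of
    per-individual displacement tolerance (conditional modes and
    repeatability from flight-initiation-distance assays), stratified
    occurrence counting with exposure offsets, Poisson occurrence-count
    regression with cluster-bootstrap or random-slope GLMM inference and
    posterior-style summaries (highest density intervals, region of
    practical equivalence, probability of direction, Bayesian R-squared),
    and association-matrix construction with Mantel comparison and
    weighted network centralities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    igraph,
    jsonlite
Suggests:
    glmmTMB,
    vegan,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
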