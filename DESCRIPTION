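Package: scdforecast
Title: Dynamic Bayesian Network Risk Scores for Subjective Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using discrete, time-homogeneous dynamic
    Bayesian networks as lifestyle risk calculators for subjective cognitive
    decline (self-rated memory, learning and concentration). Intra-slice
    structure is learned by exhaustive search under an expert node ordering
    with the quotient normalized maximum likelihood (qNML) score; lifestyle
    variables carry hardwired temporal self-edges between 5-year slices.
    Conditional probability tables are estimated on available cases with
    Dirichlet(1/2) smoothing. Exact per-slice inference with maximum a
    posteriori state propagation drives a what-if scenario calculator with
    odds ratios and Bayesian credible intervals, a dynamic decision heatmap,
    and grouped k-fold cross-validated AUROC evaluation. A configurable
    synthetic longitudinal cohort generator with categorical Markov
    persistence, planted outcome effects, item missingness and attrition
    provides reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
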