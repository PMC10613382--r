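Package: pimnet
Title: Patient-Sharing Practice Networks and Prescribing Appropriateness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how a physician practice's position
    in a regional patient-sharing network relates to the appropriateness of its
    prescribing for senior patients. Builds practice networks from claims data
    by projecting the patient-practice bipartite graph with a shared-patient
    tie threshold, computes node- and network-level measures (degree,
    betweenness, eigenvector centrality, density, average path length, and a
    random-graph baseline), scores potentially inappropriate medication (PIM)
    use per senior patient from a configurable diagnosis-to-drug-class rule
    table together with an age-adjusted Charlson comorbidity index, and fits
    pooled negative binomial regressions with heteroskedasticity-robust
    standard errors to report incidence rate ratios by within-region
    centrality quartile. Includes a synthetic claims generator with a planted,
    configurable centrality-to-PIM association, two sensitivity analyses
    (under-65 network remap; raised tie threshold), and publication-style
    descriptive reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    Matrix,
    sandwich,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
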