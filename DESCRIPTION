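Package: comorbnet
Title: Comorbidity Network Analysis of ICD-10 Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds disease comorbidity networks from longitudinal ICD-10-coded
    claims data, following the case-control design used in pediatric
    orthopaedic epidemiology: incident-case definition with a washout period,
    annual incidence rates by sex, 1:3 propensity-score matching on age, sex
    and length of pre-diagnosis record history, Haldane-Anscombe-corrected
    odds ratios with exact Fisher screening at the three-character ICD-10
    category level, clinically motivated regrouping of significant clusters,
    and construction and export (GraphML/GEXF) of the odds-ratio-weighted
    comorbidity network. A seeded synthetic claims generator with configurable
    marginal prevalences and planted case-control odds ratios supports
    validation of every stage without access to a real claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    xml2,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
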