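Package: topicscep
Title: Scoring and Validation of the TOPICS Preference-Weighted Composite Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the TOPICS-CEP preference-weighted composite endpoint
    for health-related quality of life of older persons from its 42 item
    responses (reverse coding, component aggregation with pro-rating of
    partially missing components, preference weighting and 0-10 index
    transformation), together with Dutch-tariff EQ-5D utilities and Cantril
    ladder scores.  Provides the accompanying validation toolkit: per-project
    Pearson correlations pooled by Fisher-z DerSimonian-Laird random-effects
    meta-analysis (convergent validity), random-intercept linear mixed models
    with a 15 percent change-in-estimate rule (known-group validity),
    floor/ceiling summaries, and a seeded multi-project synthetic data
    generator emulating the pooled multi-study structure of TOPICS-MDS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
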