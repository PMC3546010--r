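Package: bcepisodes
Title: Episode Derivation and Rule-Based Classification of Positive Blood Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives bloodstream-infection episodes from positive blood culture
    records and hospital-administrative contact data, and classifies each
    episode with deterministic rules: contamination versus bloodstream
    infection (repeat-growth screen over common skin commensals),
    monomicrobial versus polymicrobial, community- versus hospital-onset
    (admission time-offset windows with intra-hospital transfer handling), and
    healthcare association (prior hospital contact within 30 days). Builds
    physician-anchored reference episodes from recorded clinical assessments,
    links them to the algorithmic episodes, and evaluates concordance with
    2x2 agreement tables, percent agreement, Cohen's kappa with Landis-Koch
    interpretation bands, and crude 30-day-mortality odds ratios. Includes a
    synthetic registry generator that plants episode classes by construction,
    so the whole pipeline can be exercised and validated without access to
    real patient registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
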