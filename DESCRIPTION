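Package: iatpower
Title: IAT D-Scoring, Exclusion Cascades, Moderated Regression and
    Simulation-Based Power Analysis for Rich-Poor Implicit Bias Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analyses of implicit pro-rich
    bias measured with the Implicit Association Test (IAT). Implements the
    improved 9-step D-score algorithm, the Project-Implicit style
    participant-level exclusion cascade (eight latency/error criteria plus
    ordered demographic-completeness exclusions), scoring of fourteen
    explicit rich-versus-poor difference measures including a weighted
    attitudinal ambivalence index, the Gender x Income x Education moderated
    regression with simple-slope decomposition, and Monte-Carlo power and
    sensitivity estimation for all model tests. A synthetic trial-level
    cohort generator emulating the structure of the Attitudes, Identities
    and Individual Differences (AIID) study makes every stage testable
    without access to the original data.
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
    car,
    optparse
Config/testthat/edition: 3
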