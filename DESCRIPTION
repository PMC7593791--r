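Package: clubnet
Title: Rich-Club and Diverse-Club Analysis of Brain Functional Connectomes
Version: 0.1.0
Authors@R:
    person("clubnet", "developers", email = "clubnet@example.org",
           role = c("aut", "cre"))
Description: Construction of subject-level brain functional networks from
    parcellated resting-state time series, small-world and efficiency
    metrics with degree-preserving random-network normalization,
    rich-club and diverse-club organization (club, feeder and local
    connection strengths), overlapping-node analysis, and
    covariate-adjusted group statistics (ANCOVA, Bonferroni post hocs,
    partial correlation).  Includes a synthetic-cohort generator with
    planted modular structure, hubs and connectors so that the whole
    pipeline can be exercised and validated without access to clinical
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
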