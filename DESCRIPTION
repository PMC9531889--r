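Package: adfingerprint
Title: Regional Brain Atrophy Fingerprinting and Outlier-Based Risk Scoring
Version: 0.1.0
Authors@R:
    person("Randall", "Mercer", email = "rmercer@example.org", role = c("aut", "cre"))
Description: Derives a disease "fingerprint" of brain regions from case-control
    regional morphometry (FreeSurfer-style volumes and cortical thickness),
    using control-cohort age residualization, intracranial-volume and
    parent-structure normalization, and a bilateral significance filter on
    two-sample t-tests. Individual subjects are then scored against the
    fingerprint by region-wise z-scores and an outlier-region count, and
    classified as at-risk using the control count distribution (mean + 2 SD
    cutoff). Includes neuropsychological composite scoring and correlation
    with atrophy burden, age-by-group interaction regression, a fully
    parameterized synthetic three-cohort generator for end-to-end testing,
    and a command-line pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
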