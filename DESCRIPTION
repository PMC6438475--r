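Package: cytocascade
Title: Temporal Cytokine-Cascade Analysis for Endotoxin Challenge Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the temporal cascade of plasma cytokine
    elevations after an endotoxin (LPS) challenge from sparse blood-sampling
    schedules. Fits pass-through interpolating splines to per-animal cytokine
    time series, detects the elevation starting point as the time the fitted
    curve reaches a fixed fraction (default 5%) of its peak above-baseline
    amplitude, aligns curves at that landmark, and quantifies responses as
    effective areas under the aligned curves over the cohort's common duration.
    Includes group statistics (IQR outlier screening, one-way ANOVA with
    post-hoc Student's t tests, percent-change effect matrices), a synthetic
    LPS-challenge cohort generator with ground truth for end-to-end testing,
    and an offset-subsampling harness that certifies onset and AUC stability
    against denser sampling schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
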