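Package: mvpasim
Title: Simulation of Clinical Trials with Wearable-Derived Activity Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo simulation framework for two-arm randomised trials
    whose primary endpoint is a daily wearable-derived digital outcome
    measure (minutes of moderate-to-vigorous physical activity, MVPA).
    Generates day-level log-normal outcomes with treatment, seasonal,
    observer (Hawthorne) and interaction effects plus a participant random
    effect; applies MCAR or MNAR day-level missingness and wear-time
    compliance rules; estimates the treatment effect by baseline-adjusted
    ANCOVA of the per-participant follow-up mean; and summarises bias and
    precision of the estimator over scenario grids with Monte Carlo errors.
    Also provides reusable digital-endpoint validation statistics:
    split-period test-retest reliability (ICC), convergent-validity
    correlations, known-groups median comparisons and stability-versus-
    measurement-length curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
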