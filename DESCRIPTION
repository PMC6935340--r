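Package: nodewalk
Title: Random-Walk Modelling of Mortality Hazard Ratios over Nodal Involvement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the percentage of involved axillary lymph
    nodes relates to overall mortality in node-positive breast cancer. The
    package generates seeded registry-like cohorts, fits Cox proportional
    hazards models by Newton-Raphson maximisation of the partial likelihood
    (Efron or Breslow tie handling), sweeps dichotomisation cutoffs over the
    percentage of involved nodes to build an ordered series of adjusted hazard
    ratios, and models that series as a random walk with drift, with
    autocorrelation and portmanteau (Ljung-Box) white-noise diagnostics. An
    end-to-end pipeline writes reproducible data artifacts and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
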