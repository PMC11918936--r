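Package: fearcond
Title: Fear-Conditioning Learning Indices and Prospective Prediction of
    Emotional Distress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-day differential fear-conditioning
    experiments and relating individual differences in learning to the later
    development of emotional distress. Provides validated three-day task
    schedules (acquisition, extinction, avoidance with and without response
    cost, generalization), a synthetic-cohort generator with known latent
    learning parameters and planted diathesis-stress effects, the seven
    primary and six secondary trial-based learning indices with nonlearner
    exclusion and Z-scaling, manipulation-check statistics (within-subject
    ANOVAs, t-tests, Cronbach's alpha, normality-switched correlations),
    k-means profile clustering with gap-statistic selection of the cluster
    number, hierarchical regressions with stressor interactions, and growth
    mixture modelling of weekly impact-of-event trajectories fitted by the
    package's own EM routines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
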