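Package: behavtype
Title: Individual Behavioral Response Types: Characterization, Cluster
    Stability, and Response-Type-Balanced Experimental Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes individual behavioral response types of laboratory
    mice from repeated modified Hole Board trials and exploits them in
    experimental design. Raw ethogram variables are pooled-reference
    z-standardized and averaged into integrated scores for avoidance,
    exploration and locomotion; nuisance structure (strain, experimenter,
    test group, test order) is removed with mixed models featuring CAR(1)
    within-mouse correlation and per-stratum residual variance; the resulting
    standardized residual trajectories are partitioned by multi-restart
    longitudinal k-means with gap-statistic screening, cluster-validity-index
    k selection and bootstrap Jaccard stability. A matched-pair complete
    randomized block builder and factorial mixed-model analysis (partial eta
    squared with noncentral-F confidence intervals, Dunn-Sidak corrected
    contrasts, Cohen's d) compare designs that are balanced versus unbalanced
    on response type. A synthetic cohort generator with known latent types
    drives every stage without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    emmeans,
    glmmTMB,
    nlme,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
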