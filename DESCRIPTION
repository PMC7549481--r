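Package: jakstatpd
Title: Pharmacodynamic Transcriptomics of JAK Inhibition in Lupus Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pharmacodynamic transcriptomics in
    placebo-controlled trials of JAK inhibition in systemic lupus
    erythematosus (SLE). Covers robust summarization of probe-level
    microarray data to transcript clusters, baseline disease-versus-control
    gene ranking, per-gene mixed-model repeated-measures (MMRM) estimation
    of treatment-versus-placebo expression changes over repeated visits,
    N-of-1 single-subject interferon-signature stratification with a Monte
    Carlo test of clinical trajectories, percentile-based STAT1/STAT2
    co-elevation analysis, analysis of cytokine panels left-censored at the
    lower limit of quantification, and rule-based extraction of
    JAK/STAT-anchored interaction subnetworks. A synthetic trial generator
    with recorded ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    MASS,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
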