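Package: cytoglia
Title: Flow-Cytometry Profiling of Microglial Activation After Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the cytometric analysis of rat microglial activation
    after controlled cortical impact: hierarchical gating to isolate
    CD45+CD11b/c+P2y12+ microglia, bead-based absolute quantification,
    per-marker Mann-Whitney screening with Benjamini-Hochberg false discovery
    control, quantile-quantile distribution-shift summaries, differential
    marker correlation via Fisher-z / Cohen's q, cross-validated classifier
    discrimination with per-cell propensity scores, and tSNE embeddings.
    Includes a synthetic-cohort generator with a ground-truth manifest so the
    whole pipeline is testable without instrument data, plus FCS 3.0/3.1 and
    CSV event-table input/output with spillover compensation and arcsinh
    transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    ranger,
    e1071,
    Rtsne,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC
Config/testthat/edition: 3
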