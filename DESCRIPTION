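Package: petlat
Title: Lateralization of Temporal Lobe Epilepsy from FDG-PET Asymmetry Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for lateralizing the epileptogenic temporal lobe in mesial
    temporal lobe epilepsy from interictal FDG-PET. Computes regional
    asymmetry indices (AI = 200 * (L - R) / (L + R)) over thirteen left/right
    homologous regions of an integer-labeled brain atlas, trains entropy-based
    decision trees (C4.5 style, gain-ratio splits with error-based pruning)
    and logistic model trees (LogitBoost with simple linear base learners) to
    classify Left versus Right TLE, and evaluates models with stratified
    train/test splits, k-fold cross-validation, correct-lateralization ratios
    and Cohen's kappa with its null-hypothesis z statistic. Ships the
    published fixed classification rules as reference models and a synthetic
    PET cohort generator so the full pipeline is testable without patient
    data.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
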