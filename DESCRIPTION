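Package: biofilmdesign
Title: Experimental Design Assessment for Time-Lapse Imaging of Early Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning confocal time-lapse imaging studies of early
    biofilm colonization and antimicrobial treatment. Estimates nested
    variance components (experiment, field of view, time) from long-format
    surface-coverage measurements with a linear mixed model, quantifies
    within-series serial correlation and its variance inflation factor,
    computes log reductions against matched controls, and predicts the
    standard error and one-sided margin of error of candidate designs
    (numbers of experiments, fields of view, and frames per hour), including
    minimal-design search, quadratic variance-vs-log-reduction trends,
    hierarchical synthetic-data simulation, and bootstrap validation of
    design recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
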