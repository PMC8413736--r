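Package: antnets
Title: Scoring, Reliability and Group Inference for the Attention Network Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for trial-level Attention Network Test (ANT) data:
    balanced schedule generation for the child ANT design, an ex-Gaussian
    trial-level cohort simulator, trial exclusion and per-condition
    summaries (median correct reaction time and proportion of errors),
    Donders-subtraction alerting/orienting/executive network scores with a
    balanced speed-accuracy composite, permutation split-half reliability with
    Spearman-Brown correction, and a mixed-design inference layer implemented
    from first principles (Welch t with Holm adjustment, Cohen's d, chi-square,
    split-plot repeated-measures ANOVA with Mauchly's test,
    Greenhouse-Geisser correction and generalized eta squared, pooled-error
    post hoc contrasts, and Cook's distance screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    knitr
Config/testthat/edition: 3
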