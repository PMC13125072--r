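Package: vitalwatch
Title: Context-Aware Vital-Sign Monitoring Simulation and Classifier Benchmark
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying rule-based and probabilistic patient-monitoring
    systems on synthetic vital-sign cohorts. Generates reproducible cohorts of
    virtual patients with class-conditional physiological signals, missingness
    and noise; evaluates per-vital threshold rules (fever, tachycardia,
    hypotension, and related sensor-agent alerts) with Tell-message emission;
    performs exact marginal inference over small probabilistic-logic programs
    by possible-world enumeration; runs a tick-based multi-agent escalation
    simulation with patients, doctors and sensor agents; and benchmarks five
    classifiers implemented from their defining update equations (Gaussian and
    multinomial naive Bayes, a decision table, ridge logistic regression and a
    sequential-minimal-optimization support vector machine) with a confusion,
    ROC/PR, Matthews-correlation and McNemar evaluation suite, Youden
    thresholding and a three-level alert mapping.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
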