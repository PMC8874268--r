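Package: hrvactr
Title: Heart-Rate-Variability-Driven ACT-R Declarative Memory Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a biofeedback advertisement system:
    an ACT-R declarative-memory model whose retrieval-noise parameter is
    modulated in real time by heart-rate variability (HRV), either
    synchronized with the user's arousal or counterbalanced against it
    (homeostatic inversion). Includes conversion of browsing-history logs
    into a declarative-memory chunk store (with X-means digitization of
    visit times), base-level and spreading activation with Gaussian
    retrieval noise, windowed HRV extraction from R-R interval streams,
    a closed-loop 5-second presentation engine, seeded synthetic-data
    generators for browsing logs and R-R interval streams, and the
    behavioral analysis harness (switch and unique-image counts, exact
    Wilcoxon rank-sum tests, Spearman correlations, and post-hoc power
    for the Wilcoxon-Mann-Whitney test).
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
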