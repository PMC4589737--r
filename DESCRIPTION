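Package: phasefit
Title: Multiphasic Dose-Response Modelling by Products of Hill Phases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits mono-, bi- and tri-phasic dose-response curves with a
    generalized model in which each phase is an independent Hill process and
    the observed response is their Bliss-style product. Provides a
    replicate-weighted least-squares objective, multi-start estimation with
    simplex, separation-constrained simplex and least-squares trust-region
    optimizers, automated BIC-ranked selection among four candidate phase
    configurations, derived metrics (effective concentrations, interpolated
    effects, area under the curve), a tabular reader/writer for the
    concentration-by-replicate layout, a batch screening mode, and a
    synthetic curve and screen generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
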