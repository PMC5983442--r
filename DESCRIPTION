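Package: anfbudget
Title: Nitrogen Budgets from 15N2 Incubations, Soil Incubations and Plot Mass
    Balances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying associative nitrogen fixation (ANF) and
    internal nitrogen cycling in perennial grass systems. Computes dinitrogen
    fixation rates from closed-vial 15N2 tracer incubations (headspace
    atom-excess mixing model, per-gram normalization, detection flooring and a
    tracer-contamination false-positive bound), net nitrogen mineralization and
    nitrification from paired KCl-extraction incubations, plot-level annual and
    cumulative nitrogen mass-balance ledgers with standard-error propagation,
    and areal/annual scaling of incubation rates via bulk density, core depth,
    a glucose-stimulation correction and a growing-season partition. Includes
    weighted least-squares fitting and AIC-based selection among linear,
    exponential, power, logarithmic and quadratic-plateau response models
    (agronomic optimum estimation), and a synthetic-study generator that
    emulates a two-site randomized complete block fertilization experiment so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    pracma,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
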