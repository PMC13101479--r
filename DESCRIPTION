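Package: switchrate
Title: Rate Inference and Biosensor Statistics for Tunable Cre-lox Switching Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing low-rate Cre-lox recombination reporters used as
    whole-cell biosensors. Simulates switching populations (exact stochastic jump
    process whose mean-field limit is the logistic fraction dynamics), synthesises
    flow-cytometry event tables and plate-reader growth/fluorescence series, derives
    control-based cytometry gates and estimates rare fluorescent-cell fractions with
    binomial errors, blank-corrects and normalises plate-reader kinetics, estimates
    per-hour recombination rates by identifiability-aware logistic/exponential model
    selection (maximum likelihood, ensemble MCMC, corrected Akaike information
    criterion), and computes biosensor detection statistics (Welch tests combined by
    Fisher's method), leakage, serial-passage generation accounting, and reporter
    stability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
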