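Package: msdmets
Title: Hybrid Markov-System-Dynamics Modelling of Metabolic Syndrome Natural History
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the natural history of metabolic syndrome
    (MetS) as a 12-state multistate process over triennial examination waves.
    Estimates discrete-period transition-probability matrices from longitudinal
    panel data by count-based row normalisation, derives per-tier control and
    failure rates from intervention strata, and predicts state occupancies and
    progression-to-MetS rates with two engines: a discrete-time Markov chain
    (matrix powers, absorbing MetS) and a system-dynamics stock-and-flow
    simulation whose inter-tier flows are modulated by the control/failure
    rates. Includes a synthetic cohort generator with known ground truth for
    testing estimators, bootstrap standard errors for transition probabilities,
    and a hold-out validation protocol (mean difference, mean standard error,
    two-sample Kolmogorov-Smirnov, R squared) for comparing the two engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
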