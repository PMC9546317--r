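Package: flunixinpk
Title: Population Pharmacokinetics and Detection-Time Simulation for
    Flunixin in Horses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for medication-control pharmacokinetics of intravenous
    flunixin in horses. Implements the analytic three-compartment
    mammillary disposition model with multiple-dose superposition and a
    plasma-proportional urine model, lognormal inter-individual
    variability with a combined additive and proportional residual-error
    model, nonlinear mixed-effects estimation by Laplace approximation
    with empirical Bayes eta estimates and nonparametric bootstrap
    precision, and Monte Carlo simulation of virtual horse populations to
    derive regulatory quantities: effective and irrelevant plasma and
    urine concentrations (EPC, IPC, IUC), detection-time quantiles under
    plasma and urine screening limits, and 95/95 bootstrap
    tolerance-limit withdrawal times. A synthetic-data generator
    reproduces the two-arm study design (single and repeated daily
    intravenous bolus dosing with rich plasma and urine sampling) so the
    full analysis pipeline can be exercised without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
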