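Package: ncmscea
Title: Lifetime Cost-Effectiveness Analysis of China's New Rural Cooperative Medical Scheme
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for evaluating China's New Rural
    Cooperative Medical Scheme (NCMS) against a no-insurance comparator over
    the lifetime of a cohort of 20-year-old rural residents. Implements a
    two-arm, three-state (normotensive, hypertensive, dead) annual-cycle
    Markov cohort model with discounted cost and QALY accounting, program
    cost decomposition from the health-expenditure growth rate, labor
    productivity offsets, incremental cost-effectiveness ratios with
    willingness-to-pay classification, one-way (tornado) sensitivity
    analyses over parameter bounds, and a seeded Monte Carlo probabilistic
    sensitivity analysis with triangular parameter distributions, quadrant
    probabilities and cost-effectiveness acceptability curves. Includes a
    synthetic-data module (Gompertz-Makeham life tables, logistic
    hypertension incidence) so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
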