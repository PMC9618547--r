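Package: smacea
Title: Cost-Effectiveness Modelling of Gene-Based Therapies for Spinal Muscular Atrophy Type I
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state Markov cohort model for evaluating the
    cost-effectiveness of onasemnogene abeparvovec (AVXS-101) and nusinersen
    against standard of care in infants with spinal muscular atrophy Type I.
    Provides survival-based transition probabilities (parametric
    extrapolation with AIC/BIC/Cox-Snell model selection, Kaplan-Meier
    pseudo individual-patient-data reconstruction from digitised curves and
    risk tables), discounted cost and QALY accumulation with half-cycle
    correction, incremental cost-effectiveness analysis, one-way and
    probabilistic sensitivity analysis with acceptability curves, and
    willingness-to-pay threshold pricing, plus generators for synthetic
    trial data and life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
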