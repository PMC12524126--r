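Package: ptsdcea
Title: Markov Cohort Cost-Effectiveness Modelling of PTSD Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cohort state-transition (Markov) cost-effectiveness analysis of
    adjunctive neurofeedback versus psychotherapy and pharmacotherapy for
    post-traumatic stress disorder. Provides a quarterly-cycle cohort engine
    over CAPS-5 severity bands with dropout, relapse, retreatment and death
    dynamics; a linear CAPS-5 to EQ-VAS utility mapping for QALY accrual with
    annual discounting; probabilistic sensitivity analysis (incremental
    cost-effectiveness scatter, dominance fractions, acceptability curves);
    deterministic one-way sensitivity with tornado ordering and threshold
    solving; a schema-validated scenario file format with base-case fixtures;
    and a patient-level microsimulation that serves as a brute-force oracle
    for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
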