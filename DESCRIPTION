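Package: pepstress
Title: Pre-Ejection Period Stress Reactivity and Cuff-Less Blood Pressure Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the cardiac pre-ejection period (PEP)
    under rest, mental and physical load and for propagating PEP variability
    into the uncertainty of pulse-wave-velocity based blood-pressure
    estimation. Provides a seeded synthetic cohort generator emulating the
    statistical structure of a laboratory stress protocol (Trier Social
    Stress Test and incremental recumbent ergometry), beat- and
    measurement-level quality-control filters, stress-response and
    correlation statistics, a subject-wise cross-validated k-nearest-
    neighbour load-state classifier on (delta PEP, delta heart-rate)
    features, and a pulse-arrival-time decomposition (PAT = PEP + PTT)
    against pluggable pulse-wave-velocity/blood-pressure relations with
    1-SD/2-SD confidence bands and strategy comparisons for neglecting,
    estimating or calibrating away the PEP.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
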