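Package: adpkdsim
Title: Patient-Level Simulation of Disease Progression in Autosomal
    Dominant Polycystic Kidney Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annual-cycle, patient-level stochastic simulation of autosomal
    dominant polycystic kidney disease (ADPKD) progression. Log-linear
    annual-change equations predict total kidney volume (TKV) growth and
    decline in estimated glomerular filtration rate (eGFR); simulated
    patients advance through chronic kidney disease stages until end-stage
    renal disease (eGFR below 15) or death. Includes multivariate-normal
    sampling of equation coefficients, truncated-normal baseline cohort
    generation from summary statistics, gender-specific life-table
    mortality with a synthetic UK-like generator, and cohort-level outcome
    reporting: age at ESRD onset, CKD stage occupancy, cumulative
    incidence by age, trajectory prediction intervals, and scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
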