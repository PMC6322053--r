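Package: airsurv
Title: Air Pollution Exposure Fusion and Cohort Mortality Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A national-scale surveillance pipeline for long-term health effects
    of ambient air pollution. Fuses chemical-transport-model concentration fields
    with monitoring-station observations by kriging with external drift, upscales
    the fused fields to municipality-level annual exposures with built-up-area
    weighted block averaging, builds cumulative-mean risk-set exposure series,
    classifies ICD-9/ICD-10 coded death and hospital-admission records into cause
    groups with incident-event washout rules, checks record-linkage completeness
    against expected event counts, and estimates exposure hazard ratios with
    time-varying Cox proportional hazards models using cluster-robust variance
    for two-stage survey samples. Includes a synthetic-world generator with known
    ground truth so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
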