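Package: screentriage
Title: AI-Score Triage Simulation for Tomosynthesis Breast Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates breast-cancer screening programs in which a continuous
    examination-level AI risk score (0-10) triages each woman to reading of
    either the fast synthetic mammogram (SM, low risk) or the full digital
    breast tomosynthesis examination (DBT, high risk). Provides a synthetic
    cohort generator calibrated to published stratum fractions, a deterministic
    fixture cohort that reproduces the published per-stratum worked examples, an
    engine that evaluates the four single/double-reading workflow combinations
    at any threshold and sweeps the threshold grid for workload, recall and
    cancer-detection curves, and a clinic-level model converting reading volumes
    into full-time-equivalent radiologist requirements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
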