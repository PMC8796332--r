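Package: wisnstaff
Title: Workload-Based Health Workforce Requirements (WISN) with
    National-Level Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes facility-level staffing requirements with the WHO
    Workload Indicators of Staffing Needs (WISN) method from annual
    service volumes, support-activity allowances and additional-activity
    times; models nationally representative per-centre requirement
    thresholds with population-averaged (GEE) Poisson regression under
    independence, exchangeable and AR(1) working correlations selected by
    QIC; projects thresholds against state staffing tables into workforce
    shortage, workload-pressure and sanctioning metrics; and quantifies
    agreement between sanctioned posts and workload-based requirements
    with Lin's concordance correlation and rank correlations.  Includes a
    synthetic facility-panel and state-table generator so the full
    pipeline is testable without external survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
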