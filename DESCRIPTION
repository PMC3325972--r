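Package: duisurvey
Title: Venue-Based Probability Sampling and Design-Based Estimation of
    Drink-Driving Intention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing stratified
    three-stage cluster samples of clients leaving alcohol outlets, as used
    to estimate the prevalence of intention to drive under the influence
    (DUI) among drivers who drank on the premises.  Census enumeration
    areas are selected with probability proportional to outlet counts,
    outlet-by-shift combinations with probability proportional to squared
    shift duration, and exiting drivers by inverse (quota-stop) screening
    with a one-in-four rule for drivers not intending to drive.
    Horvitz-Thompson base weights, post-stratification calibration to 24
    cells, domain estimation of totals and prevalences with
    ultimate-cluster standard errors that account for calibration
    residuals, and a synthetic-city generator with exact ground truth for
    Monte Carlo validation are included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
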