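Package: circavar
Title: Intraindividual Variability of the Circadian Rhythm of Heart Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies day-to-day (intraindividual) variability of the
    circadian rhythm of heart rate from long-term wearable recordings.
    Gappy beats-per-minute series are interpolated and split into runs,
    the ~24-h oscillation is isolated from each run by singular spectrum
    analysis, the Hilbert transform yields an instantaneous circadian
    phase used to split the rhythm into daily cycles, and per-cycle
    period, acrophase, and amplitude are summarised over consecutive
    7-day segments into per-participant averages and variabilities.
    Includes a synthetic cohort generator with known ground truth for
    validation by parameter recovery, and the nonparametric group,
    correlation, and paired seizure-segment analyses used to compare
    people with epilepsy against controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
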