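Package: ctgdiag
Title: Rule-Based Diagnostic Engine for Cardiotocography Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated interpretation of cardiotocograms (paired fetal
    heart rate and uterine contraction recordings). Cleans and smooths
    both channels, estimates the heart-rate baseline and uterine resting
    tone, extracts the clinical key points of each contraction cycle and
    deceleration episode (cycle start/peak/end, fall start, nadir,
    recovery, shoulder region), and classifies six abnormality patterns
    (tachycardia, bradycardia, early/late deceleration, variable
    deceleration types A and B) against obstetrician-customisable
    thresholds loaded from an XML criteria profile. Includes a seeded
    synthetic trace generator with ground-truth annotations so the whole
    engine can be exercised without clinical recordings, and a
    command-line interface for batch diagnosis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
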