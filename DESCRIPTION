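Package: coralproj
Title: Probabilistic Projections of Coral Cover Under Ocean Warming and
    Acidification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples statistically downscaled sea-surface temperature
    projections with an annual coral growth and mortality model to produce
    ensemble probability estimates of shallow-water coral cover change.
    Implements site climatology and bleaching thresholds, cubic
    temperature-growth curves, aragonite-saturation scaling of
    calcification, degree-heating-month driven episodic mortality with
    threshold adaptation, bias correction and seasonal rescaling of
    climate-model output, Monte Carlo and multi-model ensemble projection,
    and a normalized-variance parameter sensitivity protocol. Ships a
    synthetic-data generator so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
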