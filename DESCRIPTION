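Package: pumppass
Title: Fish-Friendliness Assessment of Axial Flow Pumps from Barotrauma
    Sensors and Fish Passage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistics for live-fish and sensor-based
    assessment of fish passage through axial flow pumping stations.
    Converts three-channel barotrauma-detection-sensor pressure traces
    (100 Hz, hPa) into per-passage decompression metrics (pressure nadir,
    log ratio pressure change, maximal rate of pressure change) and
    time-normalized passage profiles; estimates shear strain rates from
    lateral pressure differentials and the duration spent above the
    500 1/s injury threshold; encodes fish observations into standardized
    injury classes (NEN 8775) and survival states with cohort accounting;
    and fits the associated statistical layer (length ANOVA with Tukey
    contrasts, CART survival trees, stepwise-AIC logistic and multinomial
    injury models, pump-type contrasts, Kruskal-Wallis and pairwise
    Wilcoxon tests). A seeded synthetic-data generator produces
    ground-truthed sensor traces and fish cohorts so the full pipeline is
    testable without a field deployment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
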