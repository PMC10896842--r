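Package: sostim
Title: Model-Based Design of Slow-Oscillation-Targeting Transcranial
    Stimulation Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing closed-loop transcranial alternating-current
    stimulation (tACS) protocols that selectively target global sleep slow
    oscillations (SOs). Detects SO events in stage-scored multichannel sleep
    EEG with amplitude/duration criteria and muscle-artifact filtering,
    clusters electrode co-detection patterns into global/frontal/local SO
    types with Hamming-distance k-means, represents both sleep SOs and
    stimulation effects as time-by-region current-density matrices, trains a
    bagged decision-tree classifier of global versus non-global SOs, and
    tunes stimulation waveform parameters with a genetic algorithm against
    the average global-SO current density under ANOVA-F feature weights.
    Includes a synthetic-data module (planted-SO EEG, labeled current-density
    datasets, linear montage-to-region transfer operators) so the whole
    pipeline can be exercised and validated without access to restricted
    sleep recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
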