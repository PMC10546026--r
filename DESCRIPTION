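Package: photolag
Title: Trigger-to-Display Latency Estimation from Photodiode Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the latency between stimulus triggers sent by
    presentation software and the physical appearance of the stimulus on a
    display, using a photodiode channel recorded alongside EEG in
    BrainVision format. Implements threshold-based onset detection for LED
    screens (step waveforms) and for head-mounted displays (refresh-rate
    peak trains), pairs detected onsets with sent markers, and summarises
    per-event latencies with means, standard deviations and distribution
    histograms. Ships a synthetic photodiode-signal simulator with known
    injected latencies so the full pipeline can be validated without
    hardware, plus a small command-line front end.
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
    graphics,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
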