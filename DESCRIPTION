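Package: ventsync
Title: Neural Timing-Error Analysis of Patient-Ventilator Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects neural (diaphragm electrical activity, EAdi) and
    ventilator pressurization events in paired bedside waveforms, scores
    each interaction event's trigger and cycling-off timing errors on a
    normalized -100 to +100 percent scale, classifies events as synchrony,
    dyssynchrony or asynchrony, and summarizes them as the NeuroSync index.
    Also provides pneumatic (flow/pressure) asynchrony indices for
    comparison, breathing-pattern summaries, intraclass-correlation
    reliability statistics, a pressure-support-ventilation waveform
    simulator with ground-truth event times, and dashboard-style displays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    patchwork,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
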