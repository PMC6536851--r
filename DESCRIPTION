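Package: microdyn
Title: EEG Microstate Dynamics and Dynamic Connectivity Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into quasi-stable
    scalp topographies (microstates) via topographic atomize-and-agglomerate
    hierarchical clustering (TAAHC) at global field power peaks, with temporal
    statistics (duration, occurrence, coverage, transition probabilities and a
    randomization test for non-random syntax), topographic randomization
    statistics (TANOVA), spectral summaries (dominant frequency, band powers),
    and sliding-window dynamic functional connectivity variability for network
    time courses, plus a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
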