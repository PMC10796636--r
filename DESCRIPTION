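Package: sterncells
Title: Single-Neuron Analysis of the Sternberg Working-Memory Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing human single-unit recordings collected during
    a Sternberg working-memory task and its preceding image-screening task.
    Parses TTL event streams into trials, computes behavioural statistics
    (per-load accuracy, median reaction times, repeated-measures ANOVA),
    estimates windowed firing rates and peristimulus time histograms, selects
    concept, maintenance and probe cells with permutation tests, and computes
    spike-sorting quality metrics (ISI violations, CV2, signal-to-noise
    ratios, projection test, isolation distance in a ten-dimensional waveform
    feature space). Includes a ground-truth-labelled synthetic session
    generator (inhomogeneous Poisson units with refractory dead time and
    template-plus-noise waveforms) so every stage is testable without data
    downloads, and an adapter for the NWB-style HDF5 session layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
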