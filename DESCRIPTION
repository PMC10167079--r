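Package: erpdecode
Title: Time-Resolved Decoding of Event-Related EEG Potentials with xDAWN
    Spatial Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trial multivariate pattern analysis of epoched EEG.
    Simulates multi-group event-related potential (ERP) datasets with
    age-graded P1/N1/N2/P3 components and 1/f background noise, preprocesses
    epochs (FIR band-pass, resampling, trial quality control), enhances
    evoked responses with xDAWN spatial filters obtained from a generalized
    eigendecomposition, and decodes group membership or stimulus condition
    with radial-basis support vector machines in sliding time windows.
    Includes binomial and label-permutation chance-level thresholds,
    per-participant peak-performance extraction, and between-group
    statistics (ANOVA or Kruskal-Wallis with Dunn post hocs and false
    discovery rate correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
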