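Package: cnpredict
Title: Resting-State EEG Biomarkers of Future Central Neuropathic Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting the development of central
    neuropathic pain after spinal cord injury from pain-free resting-state
    EEG. Implements relative band-power and Higuchi fractal dimension
    feature extraction, an eyes-open/eyes-closed spectral normalisation
    family that cancels participant- and site-specific amplitude scaling,
    greedy forward channel selection with nested participant-grouped
    cross-validation around LDA and linear nu-SVC classifiers, and a
    three-level generalisability evaluation (within-cohort
    leave-one-participant-out, pooled-cohort, and cross-cohort validation).
    Includes a synthetic two-site eyes-open/eyes-closed cohort generator
    reproducing the thalamocortical-dysrhythmia signature (elevated theta
    power, slowed dominant alpha rhythm, reduced alpha reactivity to eye
    opening) so the full pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
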