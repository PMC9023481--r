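Package: pwaved
Title: P Wave Detection in Normal and Pathological Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based detection of P waves in single-lead electrocardiograms,
    including pathological rhythms. QRS complexes, T waves and P waves are
    located on the phasor-transformed signal; decision rules for premature
    ventricular contractions (QRS-area thresholding), atrial fibrillation
    (symbolic dynamics and Shannon entropy of the heart-rate sequence) and
    atrioventricular dissociation adapt the P search to the rhythm context.
    Includes readers and writers for PhysioNet WFDB records and annotations,
    a synthetic ECG generator with exact ground truth for every wave, and a
    beat-level sensitivity/positive-predictivity evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
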