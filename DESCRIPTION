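Package: lcpipe
Title: Calcium Imaging Screening, Behavioral Scoring, and Fiber Photometry
    Analysis for Locus Coeruleus Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for brain-slice ratiometric (YFP/CFP FRET)
    calcium-imaging substance screens and their in-vivo follow-up in
    noradrenergic locus coeruleus neurons. Provides Y/C ratio correction and
    Z-scoring with quartile-based substance classification, full-width at
    half-maximum (FWHM) response-duration statistics, wavelet-based
    tail-suspension immobility scoring, rule-cascade vigilance staging of
    EEG/EMG/IR recordings, fiber-photometry de-interleaving with isosbestic
    (405 nm) correction and mobile-immobile epoch normalization, and
    intraclass-correlation / effective-sample-size statistics for
    animal-clustered ROI measurements. Every input can be simulated with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    nlme,
    emmeans,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
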