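Package: spsamris
Title: Responsiveness-Driven Simplification of the PsAMRIS Hand MRI Score
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for clinimetric reduction of the OMERACT Psoriatic
    Arthritis Magnetic Resonance Imaging Score (PsAMRIS). Models the full
    instrument (12 finger joints, 24 joint sites, 6 ordinal features, 144
    items) as data; computes change scores and standardized response means
    (SRMs) for the overall score and every sub-score; selects the most
    change-responsive joints to derive a simplified instrument (sPsAMRIS);
    estimates the relative efficacy of the simplified versus the full score
    with percentile bootstrap confidence bounds; and validates the reduction
    with Pearson correlation, two-way mixed intraclass correlation
    coefficients, and paired t-tests. Includes a latent-Gaussian synthetic
    cohort generator emulating a small two-timepoint, two-rater scoring
    study so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
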