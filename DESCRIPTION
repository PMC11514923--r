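Package: qt1bbb
Title: Quantitative T1 Subtraction Mapping of Blood-Brain Barrier Dysfunction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative T1 (qT1) relaxometry biomarkers of
    blood-brain barrier dysfunction in epilepsy. Simulates contrast-enhanced
    qT1 sessions on a digital brain phantom, estimates voxelwise T1 from
    variable-flip-angle spoiled gradient-echo series (DESPOT1), rigidly
    co-registers post-contrast sessions to the noncontrast volume, builds
    subtraction maps normalized by the superior sagittal sinus reference,
    reads out region-of-interest statistics, and runs cohort-level rank-based
    group comparisons (Kruskal-Wallis with Dunn post hoc tests, Glass' delta
    effect sizes) and linear regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
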