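Package: stgflow
Title: Phoneme Decoding and Directed Information Flow in Auditory Cortex ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for audiovisual speech perception experiments
    recorded with electrocorticography (ECoG). Provides a synthetic-data
    generator for trial-structured multi-electrode field potentials with
    known phoneme coding and lagged inter-electrode coupling; common-average
    re-referencing, zero-phase low-pass filtering and decimation; multitaper
    (Slepian) spectrogram estimation with per-band normalization and
    difference-spectrogram statistics; pairwise phoneme-identity decoding by
    z-scoring, train-fold PCA at 95 percent retained variance and regularized
    linear discriminant analysis under twofold cross-validation; conditional
    mutual information and directed information-tendency estimation between
    electrodes from classification confusion tables; and the accompanying
    hypothesis tests (ANOVA with Tukey contrasts, Mann-Whitney U, Wilcoxon
    signed rank against chance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
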