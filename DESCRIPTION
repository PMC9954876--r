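Package: hrventropy
Title: Sample, Fuzzy and Distribution Entropy of Heart Rate Variability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of Sample Entropy, Fuzzy Entropy and Distribution
    Entropy for beat-to-beat RR-interval series, with multiscale variants
    based on zero-phase Butterworth low-pass filtering and delay-embedded
    template vectors (no coarse-graining decimation), as well as the classic
    moving-average coarse-graining for contrast.  Includes generators for the
    benchmark bank of Gaussian white, pink and Brown noises and chaotic and
    periodic logistic-map series, a synthetic RR-interval cohort emulating
    posture- and lesion-driven changes in autonomic balance and cardiovascular
    complexity, nonparametric scale-wise group and posture comparisons
    (Wilcoxon tests with false-discovery-rate adjustment), RR-interval
    cleaning, and plain-text/CSV import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
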