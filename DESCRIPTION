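Package: hetpop
Title: Population Heterogeneity Analysis for Trial-Based Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-structured two-photon calcium imaging
    recorded during a visual go/no-go detection task. Implements a per-trial
    population heterogeneity metric (mean absolute pairwise difference of
    z-scored responses) and its multidimensional counterpart (Euclidean
    distance to the main diagonal of neural response space), together with
    the comparator metrics, hit-modulation decomposition, effect sizes, ROC
    and reaction-time statistics, naive-Bayes stimulus decoders, pattern
    consistency, noise correlations, and response-space geometry (mirroring
    and mean/heterogeneity removal) needed to relate single-trial population
    activity to detection behaviour. A synthetic session generator emulates
    the task structure (8 drifting-grating directions x 6 contrasts in
    randomised 48-trial blocks) so the full pipeline runs without external
    data and supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    jsonlite,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
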