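Package: pescar
Title: Permutation Statistics for Connectivity Analysis Between Regions of
    Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Nested sign-flip permutation testing of condition differences
    in time-frequency connectivity between two cortical regions of
    interest (ROIs) in epoched electrophysiological (MEG/EEG-style) data.
    Each ROI is subdivided into sub-ROIs, Morlet-wavelet coherence is
    estimated across epochs for every cross-ROI sub-ROI pair, per-pair
    cluster statistics on the time-frequency plane are aggregated into a
    total-connectivity statistic, and its significance is assessed against
    a condition-permutation null with Bonferroni correction over the two
    contrast directions.  Includes a synthetic-data generator emulating
    windowed oscillatory bursts embedded in structured broadband noise, a
    conventional within-ROI-averaging baseline test, and Monte-Carlo
    statistical power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
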