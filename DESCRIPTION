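Package: eegspectra
Title: Aperiodic and Periodic Parameterization of Resting EEG Spectra with
    Cluster-Based Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing resting electroencephalography (EEG) power
    spectra into aperiodic (1/f offset and exponent) and periodic (Gaussian
    peak) components, and for testing group and condition differences in the
    resulting electrode-space measures with nonparametric cluster-based
    permutation tests. Includes Welch-style power spectral density estimation
    with amplitude-based epoch rejection, total and parameterized alpha/beta
    band power, a synthetic resting-EEG cohort generator with known ground
    truth (patient/control groups, paired medication sessions, eyes-open and
    eyes-closed conditions), and an end-to-end reproducible pipeline with
    tidy tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
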