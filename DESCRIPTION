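Package: mvarconn
Title: Directed Connectivity from Multichannel Electrophysiology via
    MVAR Spectral Estimation and Stimulation-Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates directed functional connectivity from ongoing
    multichannel electrophysiological recordings (intracranial EEG and
    similar) by fitting multivariate autoregressive (MVAR) models and
    deriving frequency-resolved Granger causality, the Directed Transfer
    Function (DTF), and Partial Directed Coherence (PDC), aggregated over
    the classical EEG frequency bands.  Quantifies effective connectivity
    from single-pulse electrical stimulation (SPES) sessions through
    N1-component z-scores of averaged cortico-cortical evoked potentials.
    Includes a preprocessing chain (zero-phase high-pass filtering,
    anti-aliased downsampling, epoching, artifact-based epoch selection,
    seizure-onset-zone channel exclusion), directionality statistics over
    region pairs (two-level ANOVA with Bonferroni correction and
    one-sample t-tests on matrix asymmetries), and a synthetic generator
    of region-structured MVAR networks and SPES sessions with known
    ground-truth coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
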