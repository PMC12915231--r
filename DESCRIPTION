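Package: photocouple
Title: Dual-Site Fiber-Photometry Cortico-Striatal Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-region fiber-photometry recordings of
    motor cortex (M1) and dorsal striatum (STR) during naturalistic behavior.
    Converts raw fluorescence to behavior-locked dF/F0 with isosbestic-based
    bleaching and motion correction, applies the behavioral trial-inclusion
    rules (digging, turning, lick bouts), and quantifies cortico-striatal
    coupling by static and sliding-window Pearson correlation, absolute
    cross-correlation phase lag, plateau/peak amplitudes, binned sum-dFF
    activity with quality control, time-domain Granger causality on
    stationarity-checked vector autoregressions, and a motion-energy general
    linear model. A synthetic-session generator with known ground-truth
    coupling parameters makes every estimator verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
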