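Package: pacgrid
Title: Surrogate-Normalized Phase-Amplitude Coupling Grids with
    Cluster-Based Permutation Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state gamma phase-amplitude coupling (PAC)
    analysis of regional electrophysiological time series. Computes the
    surrogate-normalized mean-vector-length modulation index and preferred
    phase angle over a grid of low-frequency phase bands (4-12 Hz) by gamma
    amplitude bands (30-40 Hz), compares two cohorts of PAC grids with a
    cluster-based max-statistic permutation test, and summarises preferred
    phase with circular statistics. Includes a synthetic-cohort generator
    with controllable coupling strength and preferred phase for validation
    and power studies, plus delimited-text input/output and an end-to-end
    pipeline runner.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
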