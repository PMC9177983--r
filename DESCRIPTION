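Package: fretkin
Title: Simulation and Kinetic Analysis of Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing single-molecule FRET
    (Forster resonance energy transfer) time series of transcription
    elongation complexes: continuous-time Markov trace simulation with
    photobleaching and camera noise, FRET computation and bleach
    detection, hidden-Markov idealization with BIC state selection,
    regime classification and transition density plots, censored
    exponential and gamma dwell-time maximum likelihood, global
    multi-exponential photobleach-corrected decay fitting, Gaussian
    mixture decomposition of FRET histograms, and 1:1 steady-state
    binding-affinity fits. All results are returned as tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot()
    methods.
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
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
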