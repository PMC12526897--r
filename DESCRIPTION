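Package: croaker
Title: Synthesis, Inversion and Validation of Pulsed Fish Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling the pulsed vocalizations of drum fishes
    (Sciaenidae), developed around the brown croaker (Miichthys miiuy).
    Calls are synthesized as sums of amplitude-scaled, delayed and
    stretched Fejer-Korovkin (fk14) wavelet components; component
    parameters are recovered from target calls by particle swarm
    optimization with a composite correlation plus normalized-MSE
    objective; parameter influence is quantified with a normalized
    Bartlett processor and the similarity-preserving range of each
    parameter is extracted. Additional modules model inter-pulse-interval
    and sound-pressure-level variability from quartile statistics,
    assemble multipulse trains, degrade signals to target
    signal-to-noise ratios, generate labeled synthetic datasets, extract
    standard bioacoustic features (zero-to-peak SPL, IPI, energy
    spectral density), and validate reconstructions with a twin
    weight-sharing embedding network trained with a contrastive loss.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
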