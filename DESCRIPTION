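Package: trips
Title: True Richness Estimation from Fossil Occurrence Records Using a
    Poisson Sampling Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fossil sampling rates and true taxonomic richness per
    geological time interval from occurrence records, by maximum likelihood
    under a zero-truncated Poisson model of fossil sampling (the TRiPS
    approach: True Richness estimated using a Poisson Sampling model).
    Includes the occurrence-data preparation pipeline for Paleobiology
    Database style downloads (rank filtering, exclusion lists, probabilistic
    assignment of age ranges to stages, replicated count matrices), a
    continuous-time birth-death-fossilize simulator with known true richness,
    and a simulation study framework measuring confidence-interval coverage,
    bias and accuracy of the estimator.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
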