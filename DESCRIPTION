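Package: repressilator
Title: Spatially Explicit Simulation and Analysis of Repressilator Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models a three-gene repression ring (repressilator) with
    cooperative promoter binding in two complementary ways: a deterministic
    mass-action ODE system with Hopf-bifurcation scanning, and a spatially
    explicit lattice Monte-Carlo simulator in which immobile gene copies are
    placed uniformly, clustered, or segregated on a periodic lattice while
    mRNAs and proteins diffuse by random walk. Oscillatory versus stationary
    dynamics are classified by the first zero crossing of the segment-averaged
    autocorrelation function (FZCA) of protein copy-number time series, and
    replicated parameter sweeps over gene demixing, mRNA lifetime, gene copy
    number and diffusion coefficient quantify the space-induced bifurcation
    between the two regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
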