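Package: transectppa
Title: Spatial Point Pattern Analysis for Slender Benthic Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spatial point pattern analysis (SPPA) for marked organism
    annotations on narrow video-transect windows, as used to study deep-sea
    sea-pen (Pennatuloidea) assemblages and co-occurring megafauna. Provides
    pair correlation functions (homogeneous, inhomogeneous, multitype) and
    K/L functions with Ripley's isotropic edge correction for polygonal
    windows; fixed-bandwidth kernel intensity surfaces and log-linear
    inhomogeneous Poisson fitting; simulators and fitters for Thomas cluster,
    linked Thomas, hard-core and soft-core processes; Monte-Carlo quadrat
    inhomogeneity tests, simulation envelopes, Diggle's DCLF goodness-of-fit
    test and Dixon's nearest-neighbour segregation test; and a
    driver-classification ladder that maps univariate and bivariate pattern
    departures to candidate ecological drivers (habitat association,
    dispersal limitation, facilitation, competition). Includes seeded
    generators of synthetic transect scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
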