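Package: opaflim
Title: Pattern-Constrained FLIM-FRET Analysis for Multi-Exponential Donors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Time-domain FLIM-FRET analysis for donors with multi-exponential
    decays. Implements one-pattern analysis (OPA): the donor-only decay
    components (lifetimes and relative amplitudes) are calibrated once and
    frozen as a "pattern", and a third, FRET-quenched component is fitted to
    each region of interest by Poisson maximum likelihood. This separates
    BINDING (the relative amplitude of the FRET fraction, a proxy for the
    bound-molecule fraction) from FRET efficiency (a proxy for fluorophore
    proximity). Includes a TCSPC simulator with known ground truth, FLIM image
    and ROI mask I/O with pixel-exclusion rules, fast-lifetime maps, the
    legacy average-lifetime and mono-exponential-donor comparison fits, and
    group statistics (Kruskal-Wallis with Fisher's-LSD compact letter display,
    paired bleach tests, binding-acceptor correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
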