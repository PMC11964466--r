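Package: colognepop
Title: Palaeodemographic Population Estimates from Site Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Cologne Protocol for estimating hunter-gatherer
    population sizes and densities from archaeological site distributions.
    Core Areas of elevated site density are delimited by interpolating
    Largest-Empty-Circle radii over a study window, extracting density
    isopleths and selecting the optimally describing isoline; raw-material
    catchment areas (convex hulls around site buffers and lithic sources)
    provide regional quartiles that convert Core Area sizes into numbers of
    groups, people and population densities. Includes a Thomas-process
    simulator for clustered site patterns with known ground truth, readers
    and writers for delimited site tables and GeoJSON geometries, and a
    packaged reproduction fixture of published Final Palaeolithic estimates
    for Greenland Interstadial 1d-a and Greenland Stadial 1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
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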