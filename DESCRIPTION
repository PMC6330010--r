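Package: fluxtope
Title: Flux Tope Analysis for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the steady-state flux cone of a metabolic network into
    flux topes (subcones obtained by fixing the direction of every reversible
    reaction), enumerates the topes by a breadth-first search driven by linear
    programming feasibility checks, and uses the tope decomposition to
    enumerate elementary flux modes tope by tope with the double description
    method, without reaction splitting. Includes flux variability analysis for
    network consistency, flux balance analysis with enumeration of the topes
    of the optimal flux polyhedron, and post-enumeration analytics: adjacency
    structure of topes, reaction-direction frequencies, pair-direction
    coordination matrices, and Gaussian extrapolation of tope counts from
    truncated searches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    parallel,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
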