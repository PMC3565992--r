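Package: psfkit
Title: Protein Signaling Functions from Mass-Action Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms mass-action kinetic models of signal transduction
    into steady-state input-output transfer functions ("protein signaling
    functions", psfs) with explicit delays. Provides a reaction-system
    representation with scheme expansion, conservation (moiety) checking and
    a weak-reversibility validator; stiff ODE integration to a pragmatic
    steady-state criterion; single- and two-input psf sweeps with
    saturating-hyperbolic and linear fits; transmission-strength and
    EC90/EC10 saturation analysis for input-dependent modularity; a weighted
    dynamic graph export; and a discrete state-change simulator driven by
    precomputed psf lookups. Ships the published 40-reaction striatal
    dopamine/DARPP-32 signaling model as a built-in instance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    rlang,
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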