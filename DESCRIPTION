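Package: ecoevorad
Title: Eco-Evolutionary Adaptive Radiations in Competitive Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates adaptive radiations of asexual consumers competing
    for a continuous resource distribution along a one-dimensional trait
    axis.  Ecology is a trait-based generalized Lotka-Volterra model with
    Gaussian carrying-capacity and competition kernels; evolution follows
    adaptive dynamics (single mutant per evolutionary step, invasion-fitness
    and mutual-invasibility tests, equilibrium recomputation).  Species are
    delimited by trait gaps, speciation events are registered, and
    ultrametric phylogenies emerge from the branching history.  Includes
    community-structure analytics (mean and nearest-neighbor phylogenetic
    and trait distances, the Pybus-Harvey gamma statistic), experiment
    presets over a grid of competition niche widths, Newick/TSV/JSON
    exports, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), picante, withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
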