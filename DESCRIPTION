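Package: ringleaf
Title: Reaction-Diffusion Branching Morphogenesis on a Growing Leaf-Margin Ring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates branching morphogenesis of compound leaves as a linear
    activator-inhibitor reaction-diffusion system on a closed ring of margin
    cells that deforms by boundary propagation: vertex displacement along
    outward normals at pattern-coupled speeds, with cells dividing above a
    length threshold. Includes linear-stability analytics (dispersion
    relation) as an oracle for the Turing regime, morphometric analysis of
    simulated trajectories (peak detection, genealogy tracking with
    insertion/splitting classification, branch-order assignment,
    kymographs), and the combinatorial ideal-insertion theory of leaflet
    counts with its closed forms. Results are returned as tibbles and plot
    with ggplot2.
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
    rlang,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
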