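Package: vesica
Title: Bladder Wall Motion and Voiding Flow Analysis from Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates bladder-wall displacement between pre- and post-void
    surface meshes under a separable radial-motion model, derives the voiding
    time course from a real-time-imaging bladder-area curve, computes regional
    and left-right asymmetry statistics and displacement probability densities,
    and drives a simplified two-dimensional moving-boundary incompressible flow
    simulation of voiding yielding vorticity and recirculation metrics. Includes
    STL mesh input/output, a synthetic fixture generator with analytically known
    displacement fields, and tidy tabular outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
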