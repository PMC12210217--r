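Package: peptoidsolv
Title: Solvent-Resolved Analysis of Peptoid Nanosheet Self-Assembly Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis toolkit for evaporation-induced
    self-assembly of amphiphilic diblock polypeptoids in THF/water
    mixtures. Converts between solvent composition conventions and the
    mixed-solvent virtual-unit bookkeeping, computes per-molecule
    assembly energies across structure classes, characterises backbone
    conformational landscapes (internal-distance featurization, 2-D
    embedding, density-based clustering, distance-geometry
    reconstruction of mean conformations), quantifies preferential
    solvation near the peptoid surface (shell-resolved molar ratios and
    3-D density maps), and reconstructs umbrella-sampling potentials of
    mean force with a self-consistent WHAM solver. Ships a synthetic-data
    generator with known ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils,
    tools,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
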