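Package: fabind
Title: Fluorescence Anisotropy Binding Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of fluorescence anisotropy (polarization) binding
    assays for small-molecule ligands competing for a protein site.
    Converts measured anisotropy to fractional saturation with a
    quantum-yield correction, solves the exact 1:1 mass-action
    equilibrium for direct and competition titrations with full ligand
    depletion, fits dissociation constants with per-replicate
    statistics (mean +/- SEM), and scores assay quality with the
    Z-factor. Includes a synthetic plate-data generator so the whole
    pipeline is testable without instrument data.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
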