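Package: porewalk
Title: Random-Walk Diffusion Tensors and Tortuosity in 3D Porous Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo random-walk simulation of restricted molecular
    diffusion inside the pore space of digitized 3D structures such as
    binarized micro-CT volumes of tissue-engineering scaffolds and synthetic
    porous phantoms. Computes the time-dependent diffusion tensor from
    ensemble displacements, derives the apparent diffusion coefficient,
    principal diffusion directions, fractional anisotropy and the diffusion
    ellipsoid, and extracts tortuosity as the long-time asymptote of the
    normalized apparent diffusivity. Includes generators for validation
    phantoms (empty sphere, tilted cylinder, random bead packings,
    cross-hatch fibre scaffolds with tunable cell infill), preprocessing of
    grayscale volumes (median filtering, Otsu thresholding, block-average
    downscaling) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
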