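Package: kcsdr
Title: Kernel Current Source Density Estimation and Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs current source density (CSD) from extracellular
    potentials recorded with 1D, 2D or 3D electrode setups using the kernel
    CSD (kCSD) method: Gaussian or step basis sources, forward-modelled
    potential bases, and ridge-regularised kernel estimation.  Includes
    regularisation parameter selection by leave-one-out cross-validation and
    by the L-curve with triangle-area curvature, the Method-of-Images variant
    for slices on multielectrode arrays, and a quality-control toolkit:
    eigensources, error-propagation maps, measurement-uncertainty maps,
    reliability maps over families of test sources, and broken-electrode
    studies.  A seeded synthetic-data harness generates ground-truth CSD
    profiles and their forward-modelled potentials so every component can be
    validated without experimental data.
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
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
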