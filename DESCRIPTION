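Package: cryodecon
Title: Anisotropic Resolution Diagnosis and Deconvolution for Cryo-EM Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Diagnoses anisotropic resolution in single-particle cryo-EM
    reconstructions via directional Fourier shell correlation (dFSC),
    builds an anisotropic optical transfer function from the dFSC and a
    Gaussian point-spread model, and restores maps by entropy-regularized
    deconvolution. Includes MRC/CCP4 volume I/O, soft spherical mask
    generation, a synthetic phantom generator emulating preferred
    orientation (missing-cone) degradation, anisotropy metrics, and a
    smoothing/nonlinearity screening utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
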