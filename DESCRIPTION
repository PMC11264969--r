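Package: cryoclass
Title: Reference-Free 2D Classification of Cryo-EM Particle Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reference-free 2D classification pipeline for
    cryo-electron microscopy single-particle images: a labelled synthetic
    dataset simulator (procedural phantom volumes, orthographic projection
    on a rot/tilt grid, noise injection to a target signal-to-noise ratio),
    preprocessing (normalisation, histogram equalisation, circular masking)
    with an optional adversarially trained denoiser, contrastive
    (instance-discrimination) representation learning with nearest-neighbour
    mining, neighbour-consistency clustering with confidence-thresholded
    pseudo-label self-training, frequency-domain in-plane rotational and
    translational alignment on polar Fourier magnitude spectra,
    probability-weighted class averaging, and clustering evaluation
    (Hungarian-matched accuracy, Fowlkes-Mallows index, normalised mutual
    information). Includes MRC/MRCS and STAR/CSV readers and writers and a
    small command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
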