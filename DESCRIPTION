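Package: pectinporo
Title: Pectin Cross-Linking and Cell Wall Porosity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links pectin homogalacturonan cross-linking to plant cell wall
    porosity through three connected analyses: a quencher-diffusion model of
    fluorescence decay (Fickian transport through a porous wall with Bruggeman
    tortuosity, coupled to Stern-Volmer quenching) with nonlinear
    least-squares fitting and porosity-ratio inference; segmentation of
    electron micrographs into pore-size distributions and a coverage-based
    porosity estimate; and detection of calcium-bridge and hydrogen-bond
    cross-links in multi-chain bead trajectories with lifetime and
    aggregate-size statistics. Seedable synthetic-data generators provide
    ground-truth fluorescence series, pore images, and trajectories so that
    every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
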