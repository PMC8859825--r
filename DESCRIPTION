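Package: nanosorb
Title: Coarse-Grained Prediction of Protein Adsorption on Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale coarse-grained modelling of rigid-protein adsorption on
    inorganic nanoparticles. Proteins are reduced to one bead per residue placed
    at the side-chain heavy-atom centroid; each bead interacts with the particle
    through a tabulated short-range surface free-energy profile (potential of
    mean force), a Hamaker dispersion term for the particle core with a
    double-counting correction, and Debye-Hueckel screened electrostatics driven
    by the measured zeta potential. Orientation scanning yields per-pose mean
    adsorption energies, simple and Boltzmann-weighted adsorption energies,
    facet averages, lowest-energy poses and contact footprints. Also computes
    interfacial hydrophobicity descriptors (immersion enthalpy, log P of the
    nanomaterial), PMF summary statistics, Lifshitz Hamaker constants, and
    validation statistics (correlations, affinity rankings) against packaged
    silver-nanoparticle reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
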