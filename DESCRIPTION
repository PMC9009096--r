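Package: npbcmd
Title: Nonperiodic-Boundary Molecular Dynamics with a Spherical Conductor-Like
    Reaction Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale molecular dynamics engine for finite (nonperiodic)
    spherical solvent droplets.  The cavity boundary carries a quasi-analytical
    conductor-like (COSMO) reaction field expanded in real spherical harmonics
    over Lebedev-Laikov quadrature grids, providing solvation energies, atomic
    forces and the energy derivative with respect to the cavity volume.  Rigid
    molecules are propagated by a quaternion velocity-Verlet integrator with a
    stochastic velocity-rescaling thermostat; constant-pressure runs use a
    weak-coupling barostat with a breathing cavity.  The package also provides
    adaptive optimization and ridge/evolutionary fitting of a boundary
    mean-field potential, structural analysis of finite-droplet trajectories
    (radial distribution functions with finite-sphere normalization, shell
    densities, continuous hydrogen-bond strength), and a snapshot-selection
    pipeline (neighbor-distance features, PCA, partitioning around medoids with
    multi-criterion cluster validation, and GRASP representative-frame
    selection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
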