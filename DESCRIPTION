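Package: oxideforge
Title: Ab-Initio-Derived Classical Force Fields for Hydrated ZnO Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct classical (Lennard-Jones plus point-charge)
    force fields for hydrated zinc oxide surfaces from electron-density
    partitioning output. Builds wurtzite ZnO slabs cut along the (10-10) and
    (1-210) nonpolar faces, assigns connectivity-based force-field atom types
    (hydroxylated, protonated and water-coordinated surface species), converts
    per-atom net atomic charges, cubed atomic moments and bond orders into
    nonbonded parameters by Tkatchenko-Scheffler volume scaling and into
    harmonic bonded parameters by Boltzmann inversion, models the resulting
    surface charge density, and provides validation estimators (radial
    distribution functions, z-density profiles, differential adsorption and
    immersion enthalpies, potential of mean force from mean-force profiles).
    A synthetic-data module generates every input class with the statistical
    structure observed in ab initio molecular dynamics of these interfaces,
    so the full pipeline is testable without external data. Reads and writes
    XYZ and GRO coordinates and GROMACS-dialect topology fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
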