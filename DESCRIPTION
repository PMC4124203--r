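Package: sqadsorb
Title: Sequential-Quenching Monte Carlo for Irreversible Adsorption on
    Patterned Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates irreversible adsorption of attractive spherical
    particles (colloids, proteins) on energetically heterogeneous 2-D
    surfaces by the sequential-quenching model: particles arrive one at a
    time, diffuse on the surface by a Metropolis random walk among frozen
    predecessors under a region-scaled triangular-well pair potential, and
    are then quenched in place. Surfaces are partitioned into stripes each
    carrying an energy factor that scales the well depth, emulating, e.g.,
    laser-ablated versus polymer-passivated regions. Includes radial
    distribution function and region-occupancy analysis over ensembles of
    realizations, synthetic reference generators (ideal gas, lattice),
    independent brute-force oracles, a parameter-sweep driver for surface
    energy scans, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
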