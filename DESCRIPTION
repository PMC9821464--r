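Package: npbrush
Title: Coarse-Grained Simulation of Polymer Brushes with Attractive Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Bead-spring (Kremer-Grest) Langevin molecular dynamics of
    end-grafted polymer brushes mixed with monomer-attractive nanoparticles,
    in planar and inside-cylinder geometries, together with the analysis
    layer used to study their temperature response: normalized monomer and
    nanoparticle density profiles, quantile brush heights, solution
    nanoparticle concentrations, h-c diagrams and the eps_b/T
    Boltzmann-factor scaling collapse. Includes system builders (random
    grafting, fully stretched initial chains, permeable cylindrical pore
    walls), a velocity-Verlet integrator with Langevin thermostat and Verlet
    neighbor lists, plain-text trajectory formats (XYZ and a
    LAMMPS-dump-compatible dialect), and a sweep/replicate orchestration
    layer with shipped presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
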