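Package: cgraft
Title: Coarse-Grained Lipid Bilayer Variants and Raft Phase Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying liquid-ordered/liquid-disordered phase
    separation (raft formation) in ternary DPPC/DUPC/cholesterol bilayers at
    MARTINI coarse-grained resolution.  Builds the standard MARTINI species
    and a family of systematically modified lipids and sterols (chain-angle
    and stiffness assimilations of DUPC, softened DPPC, a shortened rigid
    DPPC-like sterol mimic, stiffened- and extended-head cholesterol),
    emits and parses GROMACS topology includes, generates synthetic bilayer
    configurations and Brownian trajectories with controlled composition,
    domain layout, interleaflet registration, chain order and lateral
    diffusion, and implements the analysis observables used for phase
    calling: P2 chain order parameters, grid-based interleaflet domain
    correlation, local bilayer-center maps and z-profiles, tail
    interdigitation, umbrella-model headgroup coverage, shifted
    Lennard-Jones/Coulomb pair energies, mean-square displacement, and
    Ld/Lo/gel classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
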