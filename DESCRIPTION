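Package: wdpunano
Title: Structural Descriptors and Synthetic Configurations for Waterborne
    Polyurethane Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds labeled block-copolymer chain topologies for waterborne
    biodegradable polyurethane (WDPU) nanoparticles with mixed
    poly(caprolactone)/polylactide soft segments, generates seeded synthetic
    nanoparticle configurations with controllable size, radial density
    profile, anisotropy, chain stiffness and planted hydrogen-bond
    geometries, and computes the structural descriptor suite for such
    assemblies: radius of gyration, inertia-tensor eccentricity,
    probe-extended accessible surface area, radial density profiles,
    end-to-end and segment-to-segment distances, chain- and
    segment-resolved radial distribution functions, and geometrically
    detected, three-way classified hydrogen bonds. A consistent valence
    force field (CVFF) energy evaluator with analytic forces and a toy
    relaxer is included for user-supplied parameter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
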