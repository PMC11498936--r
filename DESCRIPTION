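Package: endofuse
Title: Fusion-Mode Selection and Quantification for Endosomal Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Free-energy modelling of the two modes of organelle fusion
    (explosive pore expansion versus slow bridge fusion) for pairs of
    connected vesicles, together with the measurement pipeline used to
    quantify fusion kinetics in live imaging. Builds constrained
    minimum-bending-energy axisymmetric two-lobed membrane shapes
    (spherical caps joined by a toroidal collar), evaluates Helfrich
    bending and osmotic free-energy landscapes over the neck-width /
    area-ratio shape space, generates deterministic gradient orbits and
    fluctuation-driven Langevin orbits with explosive/bridge
    classification and phase diagrams, and provides closed-form
    estimates of the bending-versus-osmotic crossover vesicle size.
    A seeded synthetic-data generator emulates vesicle size
    populations, track tables carrying merge and shrink fusion
    signatures, and FRAP recovery curves; the quantification module
    detects fusion events from tracks, computes fusion-time and
    frequency statistics, compares size distributions, and estimates
    FRAP half-recovery times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
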