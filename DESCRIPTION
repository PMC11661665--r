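Package: capsidfield
Title: Mean-Field Capsid Electrostatics and Confinement Analysis for Viral RNA Encapsidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the encapsidation of single-stranded viral RNA
    within an icosahedral capsid at a mean-field level of description. Derives
    capsid-interior radial electrostatic potentials from atomistic charge
    snapshots (solid-angle-averaged Gauss-theorem integration) and from the
    analytical Debye-Hueckel thin-shell solution; fits both against standard
    analytic forms (screened Yukawa attraction plus a WCA repulsive wall, and a
    polynomial-times-exponential cavity profile); generates the time-dependent
    spherical squeezing protocol and terminus restraints used to confine the
    chain; runs a desk-scale Langevin bead-spring surrogate to validate
    potentials and trajectory observables (gyration radius, radial nucleotide
    density, wall pressure); and implements the contact-map analysis protocol:
    per-frame Boolean base-pairing maps, contact persistence, stable contacts,
    upper-triangular Hamming distances, average-linkage hierarchical
    clustering, pseudoknot (crossing-pair) detection and dot-bracket overlap.
    Includes seeded synthetic-fixture generators for every input class so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
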