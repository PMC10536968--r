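Package: selgamd
Title: Selective Gaussian-Accelerated Molecular Dynamics on Toy Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enhanced-sampling toolkit built around selective Gaussian
    accelerated molecular dynamics (GaMD): the potential energy of a
    multi-group system is decomposed automatically into per-group bonded,
    self-nonbonded and pairwise-nonbonded terms, and harmonic boost
    potentials are applied to arbitrary user-defined acceleration regions
    composed from those terms, with optional dual (dihedral) boosting.
    Includes a leapfrog Langevin dynamics engine for analytic model
    potentials and small bead systems, the conventional-MD search /
    adaptive GaMD search / production staging protocol with on-the-fly
    boost-parameter estimation, cumulant-expansion and exponential-average
    reweighting with an anharmonicity reliability diagnostic, local
    elevation umbrella sampling (LEUS) as a grid-bias reference method,
    and conformer string-encoding analytics (cluster and transition
    counting, dwell filtering, Hamming distances, lifetime-filtered event
    detection) for quantifying sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
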