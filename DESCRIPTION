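Package: chirospect
Title: Simulation of Chiroptical Spectra of Flexible Solvated Chromophores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated quantum/classical pipeline for simulating one-photon
    absorption (OPA), electronic circular dichroism (ECD), one-photon
    emission (OPE) and circularly polarized luminescence (CPL) band shapes
    of a flexible chromophore in a hydrogen-bonding solvent. Trajectory
    snapshots are partitioned into hydrogen-bond clusters with a smooth
    geometric F-function scored against carbonyl lone-pair virtual sites;
    environment fluctuations within each cluster are propagated onto the
    electronic states by the Perturbed Matrix Method (PMM); a large-amplitude
    motion is treated on a 1-D potential by sinc-DVR; small-amplitude
    vibronic structure is generated with Vertical Gradient Franck-Condon and
    Herzberg-Teller (VG|FC, VG|FCHT) stick spectra; and the pieces are
    composed into Boltzmann-weighted, Gaussian-broadened spectra. Synthetic
    generators for every input make the full pipeline testable without
    electronic-structure or molecular-dynamics software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
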