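Package: spindec
Title: Electron-Spin Decoherence in Proton Spin Baths with Methyl Tunnelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates decoherence of a central electron spin (S = 1/2)
    coupled to a bath of proton spins, both for the bare spin observed by a
    two-pulse Hahn echo and for the dressed (spin-locked) spin observed by a
    phase-modulation primary echo during microwave irradiation. Methyl-group
    rotational tunnelling enters as an exchange coupling between the three
    protons of a methyl group, with a hindered-rotor solver that converts
    rotation barriers into tunnel splittings. Decay traces can be assembled
    by the analytical pair product approximation, by cluster correlation
    expansion (CCE), by partial CCE over disjoint cluster partitions, or by
    plain cluster factorization, with eigenbasis propagation for numerical
    stability, detection of unstable traces, and powder averaging on
    deterministic hemispherical orientation grids. A synthetic-geometry
    generator builds methyl-group and trityl-like spin systems with
    point-dipole hyperfine tensors for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
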