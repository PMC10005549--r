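Package: ringexciton
Title: Collective Optical Modes of Dipole-Coupled Quantum Emitter Nanorings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models N-fold rotationally symmetric rings and concentric
    multi-ring stacks of two-level quantum emitters coupled through the
    free-space electromagnetic vacuum. Builds the coherent and dissipative
    dipole-dipole coupling matrices from the dyadic Green's tensor,
    diagonalizes the effective non-Hermitian Hamiltonian of the
    single-excitation manifold both densely and through a Bloch-mode
    (angular momentum) symmetry reduction, and reconstructs scattered-field
    intensity maps of collective modes. Includes scripted analyses of
    subradiance scaling with emitter number, rotation-angle sweeps with
    avoided-crossing detection, and a three-ring Frenkel-exciton treatment
    of the LH2 light-harvesting antenna (B800/B850 bands).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
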