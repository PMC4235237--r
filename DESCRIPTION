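Package: orthobone
Title: Orthotropic Material Assignment for Bone Finite-Element Models via
    Volumetric Harmonic Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns per-element orthotropic material coordinate systems to
    tetrahedral bone meshes from longitudinal and radial volumetric harmonic
    fields, optionally extended with virtual finite elements over the
    alveolar-ridge region so the longitudinal field follows the true
    trajectory of maximum stiffness in dentate mandibles.  Provides the
    orthotropic elastic-tensor machinery (nine engineering constants,
    Bond rotation, Voigt-Reuss-Hill effective isotropic reduction), a
    linear-elastic constant-strain tetrahedron solver, a deterministic
    mandible-proxy geometry generator with an embedded dental implant, and
    peri-implant stress/strain reporting that compares isotropic,
    per-element orthotropic, and zoned-orthotropic material models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
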