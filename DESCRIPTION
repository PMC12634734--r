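Package: sijfem
Title: Finite-Element Simulation of Sacroiliac Joint Mechanics with
    Pre-Tensioned Ligaments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quasi-static nonlinear finite-element simulation of the
    sacroiliac joint on parametric synthetic pelvis geometry. Bone is
    modelled as inhomogeneous linear-elastic tetrahedra with a
    density-to-modulus power-law material mapping binned into discrete
    material classes; ligaments and gluteal muscles are tension-only,
    pre-loaded spring fibers; joint cartilage is represented by exponential
    or linear pressure-overclosure contact with regularized Coulomb
    friction. Includes generic and gait-phase load scenarios, surface von
    Mises stress summaries, relative joint kinematics, one-at-a-time
    normalized sensitivity analysis, perturbation and mesh-convergence
    studies, and Gmsh/VTU mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
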