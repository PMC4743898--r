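Package: ifem2d
Title: Immersed Finite Element Methods for 2D Fluid-Structure Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-boundary-fitted fluid-structure interaction on unstructured
    2D triangle meshes using the immersed finite element method family: the
    original explicit coupling, a semi-implicit variant built on an indicator
    function obtained from a Poisson problem, and a modified variant (mIFEM)
    in which the solid momentum equation is solved directly and a correction
    force constrains the artificial fluid to follow the solid.  Includes a
    stabilized equal-order incompressible (optionally pseudo-compressible)
    Navier-Stokes solver, Lagrangian solid dynamics with linear elastic,
    Kelvin-Voigt viscoelastic and Mooney-Rivlin materials, conservative
    interpolation/force-spreading kernels, parametric biomedical demo
    geometries (cell in a bifurcated microvessel, self-oscillating two-layer
    folds in a pressure-driven air channel), Gmsh mesh input and VTU output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
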