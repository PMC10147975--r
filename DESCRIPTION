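Package: ecogfwd
Title: Biomechanics-Informed Solution of the Electrocorticography Forward Problem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific pipeline for solving the electrocorticography (ECoG)
    forward problem in a brain deformed by subdural electrode implantation.
    Provides meshless total Lagrangian explicit dynamics (MTLED) with moving
    least squares shape functions for predicting brain shift under prescribed
    electrode displacements; displacement-field image warping with preservation
    of principal direction (PPD) tensor reorientation for diffusion tensor
    images; DTI-based fuzzy C-means tissue classification and anisotropic
    conductivity tensor construction; and a voxel-hexahedral finite element
    solver for the electrostatic forward problem with a full-subtraction dipole
    source. Synthetic concentric-sphere head phantoms and analytic multilayer
    sphere dipole solutions are included as validation oracles, together with
    readers and writers for NRRD images, STL surfaces, 3D Slicer fiducial files,
    Abaqus-style tetrahedral grids and legacy VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
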