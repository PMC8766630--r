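Package: rhinoflow
Title: Simulation- and Measurement-Based Diagnostics for Nasal Airflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained workflow for physics-based diagnostics in
    rhinology. Analyzes and classifies four-phase rhinomanometry
    recordings, trains small convolutional networks for binary and
    nine-class segmentation of CT-like axial slices with class-balanced
    and focal losses, post-processes label volumes and extracts watertight
    surface meshes, generates hierarchical Cartesian (octree) computational
    meshes, simulates respiratory flow and heat transfer with a D3Q27
    thermal lattice-Boltzmann solver with curved-wall, pharynx and nostril
    boundary conditions, and reduces the fields to pressure-loss,
    temperature and centerline cross-section diagnostics. Synthetic
    phantoms (ducts, two-passage airways, labeled head volumes,
    respiration waveforms) make every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    digest,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
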