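Package: hepatrunc
Title: Truncated Hepatic Arterial Trees and Hybrid Particle-Flow Modeling
    for Liver Radioembolization Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico planning of transarterial radioembolization
    (TARE) of liver tumors. Implements a tumor-informed truncation algorithm
    for hepatic arterial trees driven by a voxel region-growing perfusion
    model (tumor perfusion percentages per outlet), outlet flow boundary
    conditions from segmental liver volumes and perfusion rate constants, a
    desk-scale Lagrangian microsphere transport surrogate with Quemada
    shear-thinning blood rheology, hybrid flow-proportional redistribution of
    particles beyond truncated outlets, Particle Release Grid classification
    of injection planes, and a Monte Carlo tumor-dose distribution over
    sampled catheter tip locations. Synthetic vascular trees, tumor masks and
    inflow waveforms allow the full pipeline to run without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
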