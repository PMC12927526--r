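Package: vemtools
Title: Difficulty Metrics and Instance-Segmentation Evaluation for Volume
    Electron Microscopy Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and scoring 3D instance-segmentation
    benchmarks of organelles in volume electron microscopy. Implements two
    per-instance difficulty metrics on labeled volumes, the Dilation
    Collision Index (crowding / merge risk) and the Erosion Fragility
    Index (thin-neck / split risk), a two-tier evaluation protocol
    (voxel-level semantic accuracy and Hungarian-matched instance-level
    accuracy at an IoU threshold), dataset-standardization operators
    (instance reindexing, minimum-volume filtering, anti-aliased
    resampling, topology checks), NIfTI label/image I/O with an
    nnU-Net-compatible dataset layout, and a seeded synthetic phantom
    generator with controlled prediction perturbations for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    igraph,
    clue,
    digest,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
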