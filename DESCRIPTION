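Package: bioprintqc
Title: Spatially Resolved Defect Characterization and Fidelity Assessment
    for Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Layer-wise quality control for extrusion 3D (bio)printing
    monitored by optical coherence tomography (OCT). Parses GCode toolpaths
    and rasterizes them into per-layer target model maps with calibrated
    filament geometry, reconstructs printed-thickness maps from OCT-style
    surface data referenced to a base-platform acquisition, classifies
    per-pixel print state (normal, under-extrusion, over-extrusion, filament
    breakage, stringing), scores structural fidelity by mean SSIM, and emits
    secondary-printing GCode that repairs breakage and under-extrusion runs.
    Includes a synthetic scaffold simulator with ground-truth defect
    annotations so the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
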