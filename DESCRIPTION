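Package: memdeform
Title: Membrane Deformation Analysis for Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics trajectories of lipid
    bilayers interspersed with transmembrane core proteins (syndecan-4
    style systems under shear flow). Rasterizes leaflet head-group heavy
    atoms into rectangular height maps, computes per-frame top/bottom
    deformation statistics, classifies grid cells into hill/valley
    deformation categories, estimates inter-leaflet strain rates and net
    surface forces, quantifies protein-proximal membrane lift, and compares
    simulation cases with mean +/- SE summaries and one-way ANOVA. Includes
    a ground-truthed synthetic bilayer-trajectory generator so the full
    pipeline can be exercised and validated without large trajectory files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
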