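Package: petdefect
Title: Voxel-Wise FDG-PET Defect Quantification and Longitudinal
    Metabolic Decline Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies regional brain glucose metabolism from FDG-PET
    volumes against a normative control template. Provides cerebellum-mean
    intensity normalization, Gaussian smoothing, voxel-wise Z-score defect
    mapping with gray-matter-probability atrophy correction, severity
    grading, longitudinal improved/maintained/worsened voxel
    classification, atlas-based regional metrics (metabolism intensity,
    defect extension, defect intensity), cluster-extent thresholded
    voxel-wise paired t-statistics with a placebo-derived disease
    progression mask, and longitudinal subcortical volumetry summaries.
    Includes a seeded synthetic phantom cohort generator with known
    ground-truth regional decline for end-to-end validation, and a
    pipeline orchestrator that emits per-arm summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
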