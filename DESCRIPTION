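Package: neonorm
Title: Voxelwise Normative Modelling of Neonatal Brain Images with
    Multi-Output Gaussian Processes
Version: 0.1.0
Authors@R:
    person("neonorm", "developers", email = "neonorm@example.org",
           role = c("aut", "cre"))
Description: Builds voxelwise growth charts of multi-channel volumetric brain
    images over the perinatal period. Each voxel's five outputs (two intensity
    contrasts and three displacement components) are modelled jointly with a
    multi-output Gaussian process (intrinsic co-regionalization model) over
    post-menstrual age at scan, gestational age at birth and sex, using a
    linear + squared-exponential + white kernel sum. Out-of-fold deviation
    (Z) maps expose individual differences: punctate lesions are detected
    with a patch-based zeta anomaly score (per-voxel k-means over reference
    patches), and individuals are re-identified longitudinally by deviation-
    map correlation. Includes a fully synthetic cohort generator, global
    shape modelling via affine stretch/shear decomposition, NIfTI-1 I/O and
    a subcommand CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
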