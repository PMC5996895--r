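Package: atlasseg
Title: Automatic Tree Learning Anomaly Segmentation of Acute Stroke Diffusion Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of the acute ischemic core lesion from
    diffusion-weighted MRI (DWI at b=1000 s/mm2, ADC map and b=0 image).
    Implements contralateral mirror-corrected feature maps via rigid
    mid-sagittal registration, a Youden-index decision tree with pseudo-count
    leaf probabilities, leave-one-patient-out AUC depth pruning, and
    morphological spatial regularization of the voxelwise probability map.
    Includes the evaluation protocol (Dice coefficient, outer leave-one-out
    cross-validation, per-patient optimal two-threshold baselines, lesion
    volume agreement) and a seeded synthetic cohort generator emulating
    bilaterally quasi-symmetric brains with one-sided diffusion lesions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
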