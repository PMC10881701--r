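Package: lobetrial
Title: Within-Patient Lobe-Randomized Radionuclide Uptake Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for within-patient randomized
    trials of intra-arterial radionuclide therapy in bilobar liver disease,
    where one liver lobe is treated intra-arterially and the contralateral
    lobe serves as the control arm. Provides a synthetic phantom and cohort
    generator (Poisson-count emission volumes over a bilobar liver with
    spherical lesions, follow-up diameters, laboratory panels), the
    voxel-level quantification chain (adaptive 42%-of-maximum lesion VOI
    segmentation, rigid VOI transfer, mean and 1-cm-sphere peak uptake,
    volume-weighted tumour-to-non-tumour ratios), permuted-block in-patient
    randomization with exact noncentral-t power calculations, the paired
    inferential battery (paired t, log-ratio test with back-transformed
    estimates, two-level random-intercept mixed models, covariate
    effect-modification tests, exact Fisher tests by complete enumeration),
    RECIST 1.1 per-lobe response classification, baseline-delta toxicity
    grading, and an end-to-end pipeline with report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
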