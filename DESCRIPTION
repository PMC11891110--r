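Package: axskel
Title: Axial Skeleton Segmentation and Bone PET Lesion Detection on Low-Dose CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation of discovertebral units, sacro-iliac joints
    and posterior spinal joints (facet, costovertebral and costotransverse) on
    low-dose CT skeletal label maps, by two complementary routes: a
    morphological method driven by the spinal cord landmark and
    dilation-overlap set algebra, and a multi-atlas method with spinal-length
    atlas selection, similarity-transform registration and majority-vote label
    fusion. The resulting volumes of interest feed a threshold-based sodium
    fluoride PET lesion-detection layer (SUVmax/SUVpeak/SUVmean,
    region-matched median-SUV backgrounds, target-to-background ratios, ROC
    analysis with Kolmogorov-Smirnov threshold selection and DeLong AUC
    comparison). A deterministic synthetic spine phantom generator makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
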