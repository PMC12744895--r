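Package: dceKMC
Title: K-Means Cluster Analysis of Ultrafast Breast DCE-MRI Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of ultrafast dynamic contrast-enhanced
    breast MRI. Fits empirical mathematical models of percent signal
    enhancement voxelwise, partitions tumor and parenchymal voxels into
    five k-means clusters by maximum enhancement rate (A*alpha), fits
    cluster-level three-parameter enhancement and extended Tofts
    pharmacokinetic models with a population arterial input function,
    and summarizes bilateral (ipsilateral/contralateral) asymmetry of
    background parenchymal enhancement kinetics. Includes a bilateral
    breast digital phantom and cohort simulator with known ground truth,
    group-comparison statistics, and exhaustive small logistic-model
    search with bootstrap ROC confidence intervals for predicting
    pathologic complete response to neoadjuvant chemotherapy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
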