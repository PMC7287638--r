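Package: fmgdual
Title: Dual-Output Deep Learning for Force-Myography Gesture Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous hand-gesture classification and finger-angle
    regression from a multichannel force-myography (FMG) wristband. Implements
    the channel-permutation movement-image augmentation (time series to square
    image encoding with pair-adjacent channel arrangements), a dual-output
    convolutional network and gated-recurrent-unit baseline trained with a
    weighted joint cross-entropy and mean-squared-error loss, shallow
    single-output benchmarks (RBF support vector machines, random forests),
    tree-importance sensor selection and ablation, leave-one-trial-out
    cross-validation with exact Wilcoxon signed-rank model comparison, and a
    seeded synthetic wristband-signal simulator with ground-truth labels and
    joint angles for end-to-end testing without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    randomForest,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
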