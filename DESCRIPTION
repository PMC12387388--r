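Package: echoplanim
Title: Planimetry and Deep-Learning Screening of Mitral Stenosis in
    Echocardiogram Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support toolkit for grading mitral stenosis from
    three-dimensional transesophageal echocardiogram videos. Implements a
    digital-image-processing planimetry engine (luminance grayscale
    conversion, single-band fixed thresholding, orifice contour extraction,
    an incremental threshold scan with a perimeter-stability stop rule) that
    measures the maximum diastolic mitral valve orifice area in square
    centimetres and grades stenosis severity, together with a companion
    image-augmentation and convolutional-neural-network arm that screens
    videos for the presence of stenosis. Ships a synthetic phantom-video
    generator with analytic ground truth so every stage is testable without
    clinical data, and reads pixel calibration from vendor on-screen markers
    (paired green dots or a scale line).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    tibble,
    tidyr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
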