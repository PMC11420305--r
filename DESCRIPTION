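Package: fundusindex
Title: Fundus Sex Index from Quantified Color Fundus Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies 42 color-fundus-photograph parameters (retinal
    vessel angles, papillomacular position, optic disc ovality ratio, and
    red-green-blue intensities with the tessellation fundus index at nine
    loci) from an image plus landmark annotations, fits an L2-regularized
    binomial logistic regression on those parameters, and summarises each
    eye by its leave-one-out cross-validated predictive value, the fundus
    sex index (0 masculine to 1 feminine).  Includes a synthetic right-eye
    fundus cohort generator with known ground truth, and the downstream
    association analyses of the index against body height and axial
    length, overall and within sex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    yaml
Config/testthat/edition: 3
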