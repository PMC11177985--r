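Package: strain2infarct
Title: Myocardial Infarct Segmentation from Left-Ventricular Strain Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Non-invasive identification of myocardial infarct regions from
    circumferential, radial and longitudinal (CRL) end-systolic strain fields
    of the left ventricle. Generates a synthetic library of strain maps with
    known infarct masks, renders them as normalized three-channel AHA bullseye
    images, and trains encoder-decoder segmentation networks (UNet, attention
    UNet, dense UNet, residual attention UNet) together with a composite
    multi-fidelity network that corrects low-fidelity predictions using scarce
    high-fidelity examples. Also provides a transversely isotropic Fung-type
    constitutive model of passive and active myocardium evaluated at a
    material point, and Green-Lagrange strain kinematics from per-frame
    displacement fields with transformation to the local CRL frame. Networks
    run on a compact CNN engine built on 'RcppArmadillo' convolution kernels
    and a reverse-mode autodiff tape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
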