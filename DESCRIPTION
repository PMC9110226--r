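Package: ctprestore
Title: Low-Dose CT Perfusion Sinogram Restoration and Perfusion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and restoration pipeline for low-dose dynamic brain CT
    perfusion. Generates a dynamic ellipse phantom with normal, penumbra,
    infarct-core and arterial tissue kinetics, forward-projects it to
    parallel-beam sinograms, injects noise following the exponential
    mean-variance model of low-dose projection data, restores sinograms by
    penalized weighted least squares with a four-neighborhood median penalty
    solved by a modified Gauss-Seidel iteration, applies adaptive
    variance-thresholded projection weighting, reconstructs frames by filtered
    back-projection, computes CBV, CBF, MTT and TTP perfusion maps, and
    evaluates restoration quality with PSNR, RMSE and the universal quality
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
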