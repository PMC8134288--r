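Package: usgan
Title: Learned Ultrasound B-Mode Rendering with Attenuation-Conditioned GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for learning ultrasound B-mode rendering from
    cross-sectional tissue label maps. Provides a seeded procedural phantom
    generator, integral acoustic attenuation maps with convex-probe scan
    conversion, a simplified convolutional B-mode reference simulator
    (speckle, directional bone shadows, boundary reflections), a conditional
    generative adversarial network translating segmentation and attenuation
    maps to B-mode images (with switchable ablations of each architectural
    component), a masked adversarial plus L1 training objective, and an
    evaluation suite including PSNR, masked MAE, a local patch chi-squared
    histogram texture metric with spatial error maps, and Frechet distances
    on pluggable image features. Convolution primitives are implemented in
    C++; training runs on a single CPU at reduced image sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    generics,
    ggplot2,
    yaml,
    png,
    tiff,
    jsonlite,
    withr,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
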