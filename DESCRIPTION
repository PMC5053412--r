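Package: ropscreen
Title: Computer-Aided Screening of Aggressive Posterior Retinopathy of
    Prematurity from Fundus Images
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens posterior-pole fundus photographs of premature infants
    for Aggressive Posterior Retinopathy of Prematurity (APROP). From a
    single RGB fundus image and a manual optic-disc annotation the package
    removes saturation artifacts, segments the retinal vessel network with
    one of three algorithms (morphological background subtraction with
    gray-level co-occurrence entropy thresholding, oriented Gaussian matched
    filters, or multiscale Laplacian voting), thins the network to a
    skeleton, prunes spurs, and measures region-restricted vessel tortuosity
    and branching. A two-class linear discriminant on the per-region feature
    pairs, validated by leave-one-out cross-validation and fused across two
    optic-disc-anchored diagnostic regions, labels each eye as APROP or
    clinically healthy. A synthetic-fundus phantom generator with analytic
    ground truth supports end-to-end validation without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
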