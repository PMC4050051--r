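Package: choroidlayers
Title: Choroidal Vessel Segmentation and Haller's/Sattler's Sublayer
    Thickness Mapping for 1060-nm 3D OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the choroidal vasculature in
    three-dimensional long-wavelength (1060 nm) optical coherence tomography
    volumes. Detects the retinal pigment epithelium/Bruch's
    membrane/choriocapillaris complex and the choroidal-scleral interface,
    segments hyporeflective choroidal vessels by cone-vote core detection and
    geodesic dilation, splits the choroid into Haller's and Sattler's layers
    from volume-to-surface voxel-ratio depth profiles, averages thickness over
    ETDRS-style macular grids, and computes repeatability statistics
    (Bland-Altman limits of agreement, absolute-agreement intraclass
    correlation, coefficients of repeatability, repeated-measures ANOVA). A
    synthetic OCT phantom with voxel-level ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    png,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
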