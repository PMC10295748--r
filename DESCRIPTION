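Package: stentmorph
Title: Serial-Grinding Reconstruction and Stent Lumen Morphometry for the
    Eustachian Tube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct serially ground, epoxy-embedded specimens of
    the stented Eustachian tube and to quantify the stent lumen. Section images
    are rigidly co-registered on the two fiducial grooves cast into the
    embedding block, stacked into a volume, and the through-plane spacing is
    corrected against a trusted reference scan. The stent lumen is segmented,
    its main axis fitted, and cross-sections perpendicular to that axis are
    measured: longest diameter, perpendicular short diameter split into its
    cartilage-facing (D1) and opposite (D2) parts, elliptical and pixel-counted
    areas, and the rotation of the long axis along the stent with 90-degree
    swap correction. Landmark-referenced position metrics (distances to the
    isthmus and the pharyngeal ostium, coverage overlap across stents) and a
    synthetic phantom generator emulating the embedded specimens complete the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
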