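Package: medfuse
Title: Hybrid CT/MRI Medical Image Fusion with Shearlets and a Siamese CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses co-registered multimodal medical image pairs into a single
    image retaining complementary bone and soft-tissue detail. Implements
    morphological bottom-hat/top-hat preprocessing, PCA-based decolorization,
    a local shift-invariant shearlet transform (undecimated tight-frame
    pyramid with Meyer-window directional filters), Siamese-CNN decision-map
    fusion of high-pass sub-bands, local-energy fusion of the low-pass band,
    guided-filter decision refinement, objective fusion-quality metrics, and
    deterministic synthetic phantom generators for offline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
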