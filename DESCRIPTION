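Package: nftquant
Title: Weakly Supervised Quantification of Neurofibrillary Tangles in
    AT8-Stained Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to bootstrap pixel-level neurofibrillary tangle (NFT)
    segmentation masks from single-point nucleolus annotations on
    AT8/DAB-stained whole-slide images. Implements colour deconvolution of
    RGB immunohistochemistry tiles to haematoxylin/eosin/DAB optical
    densities, Otsu-based DAB binarization, centre-biased blob selection
    around each point annotation, tile-to-ROI mask stitching, tile-grid
    construction with class-balanced sampling, pixel-level agreement maps
    and metrics (F1, mIOU, AUROC, Tversky index, prevalence-based random
    baseline), object-level bounding-box evaluation (merging, greedy IOU
    matching, NMS, average precision), whole-slide NFT burden scoring
    against tissue area, super-tile slicing for expert re-annotation, and
    a deterministic synthetic AT8-IHC scene generator that provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
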