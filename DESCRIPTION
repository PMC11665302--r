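Package: wsimil
Title: Attention-Based Multiple Instance Learning for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weakly supervised classification of whole-slide images (WSI)
    with attention-based multiple instance learning (MIL). Implements three
    lightweight architectures -- attention MIL with tanh-gated attention
    pooling (AMIL), additive MIL with LeakyReLU attention and a per-patch
    score layer (AdMIL), and a hybrid additive model with tanh attention --
    together with a tile preprocessing pipeline for pyramidal slides (tissue
    masking by Otsu thresholding, color-distance artifact filtering,
    hierarchical tile coordinate mapping, fraction- and cluster-based
    sampling, HED stain augmentation), a pluggable tile encoder with an HDF5
    embedding store, a cross-validated multi-seed training and AUC evaluation
    protocol, and attention / excitatory-inhibitory heatmap rendering
    ("virtual staining"). Synthetic bag and slide generators make the whole
    pipeline testable without any external cohort or pretrained encoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    png,
    rhdf5,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
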