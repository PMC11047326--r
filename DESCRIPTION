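Package: cowreid
Title: Open-Set Cattle Re-Identification with Spatial Transformer Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Open-set individual recognition of Holstein cattle from overhead
    coat-pattern imagery. Provides a synthetic coat-pattern image generator with
    identity-disjoint train/test splits and balanced verification pairs,
    aspect-ratio orientation normalization and stochastic augmentation, a
    residual embedding network with configurable attention (CBAM, SimAM, ParNet
    SSE) and a spatial transformer applied to the backbone feature maps, four
    metric-learning losses (ArcFace, CosFace, contrastive, center), and an
    open-set pair-verification module with four distance metrics, exhaustive
    threshold search, ten-fold cross-validated calibration and accuracy-weighted
    threshold aggregation. The network and its gradients are implemented
    directly on BLAS matrix operations, so the package trains small models on a
    single CPU with no external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
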