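Package: cfnet
Title: Interactome Inference from Co-Fractionation Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for inferring protein-protein interaction networks from
    co-fractionation mass spectrometry (CF-MS) experiments. Reads MaxQuant
    proteinGroups and Phospho(STY) Sites tables and CORUM- or EcoCyc-style
    complex catalogs; computes chromatogram similarity features (distance
    correlation, weighted cross-correlation, cosine similarity, mutual
    information) with measure-specific missing-value handling; trains
    cross-validated random-forest pair classifiers with precision-based
    network thresholding; supports labeled-pair data augmentation for
    training-data-poor species and cross-species classifier transfer;
    evaluates networks by Jaccard overlap, neighbor-voting functional
    coherence, per-edge coexpression and saturation analysis; prioritizes
    phosphosites by fraction-level detection with hypergeometric
    kinase-substrate enrichment. Includes a synthetic CF-MS study simulator
    with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
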