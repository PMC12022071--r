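Package: plaquemap
Title: Correlative Imaging Analysis of Amyloid Plaque Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking amyloid-beta plaque morphology to peptide
    chemistry in correlative fluorescence-microscopy / MALDI mass-spectrometry
    imaging (MSI) experiments. Provides a synthetic-cohort generator with
    known ground truth (plaque-morphotype image scenes, MSI datacubes,
    multi-patient cohorts), LCO-channel plaque segmentation and per-ROI
    fluorescence quantification, a convolutional neural-network morphotype
    classifier trained by three-fold cross-validated ensembling, the ROI
    spectral-processing chain (square-root transform, Savitzky-Golay
    smoothing, SNIP baseline estimation, MAD noise, TIC normalization,
    SNR-gated trapezoidal peak areas), bisecting k-means spatial segmentation
    of MSI datacubes, landmark-based microscopy-to-MSI registration and
    plaque-load summaries, and the statistics layer (OPLS-DA with VIP scores,
    Ward hierarchical clustering, Kruskal-Wallis with Dunn post-hoc tests,
    Mann-Whitney/Wilcoxon with Benjamini-Hochberg adjustment, correlation and
    coefficient-of-variation summaries), plus end-to-end pipeline
    orchestration evaluated against the simulator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mclust,
    pracma,
    signal,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
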