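Package: rmma
Title: Analysis of Raft Membrane Microarrays by MALDI-MS Imaging and
    On-Chip Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of raft membrane microarrays (RMMAs):
    simulation of MALDI mass-spectrometry imaging datasets and assay scans
    with known ground truth; imzML and layout input/output; spectrum
    preprocessing (TIC normalization, alignment by binning, relative-intensity
    peak filtering, ppm annotation matching, replicate-correlation outlier
    detection); spatial-spectral segmentation by divisive analysis with a
    random-walker (personalized-rank) competition split and correlation-scale
    coloring; per-spot representative spectra via divisive clustering;
    multivariate discrimination (ANOVA feature ranking, PCA with a cumulative
    variance selection rule, cross-validated k-NN, naive Bayes, random forest
    and neural-network classifiers); and protein-normalized quantification of
    colorimetric assay readouts with standard-curve fitting and
    deviation-factor outlier removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    xml2,
    tiff,
    class,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
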