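Package: kappaMSI
Title: Multimodally Corroborated Spatial Segmentation for Mass Spectrometry Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating regions of interest in mass spectrometry
    imaging (MSI) experiments by corroborating MSI-based spatial segmentation
    with segmentation of a co-registered H&E histology image. The whole-slide
    image is tiled at the MSI pixel size and each tile is encoded as a
    histomorphological feature spectrum; both modalities are clustered by
    spectral clustering, and the number of clusters is selected by maximizing
    the permutation-aligned Cohen's kappa between the two segmentations.
    Includes imzML ingestion, mass-spectral preprocessing, NMF score-map based
    affine + B-spline registration with a mutual-information metric, internal
    cluster-validity baselines (edge-correlation and Davies-Bouldin), fusion of
    the two segmentations into confidence-masked ROIs with characteristic-ion
    rankings, and a paired-phantom simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    jsonlite,
    rhdf5,
    EBImage,
    png,
    tiff,
    signal,
    clue,
    uwot,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: MassSpectrometry, ImagingMassSpectrometry, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
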