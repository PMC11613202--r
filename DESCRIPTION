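Package: fluorounmix
Title: Attenuation Correction and Unmixing of Hyperspectral Fluorescence
    Spectra for PpIX Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies protoporphyrin IX (PpIX) in hyperspectral
    fluorescence data from 5-ALA guided brain-tumor surgery. Implements the
    classical dual-band attenuation correction with non-negative
    least-squares unmixing against a five-fluorophore endmember library, a
    supervised residual 1D convolutional network (ACU-Net) trained with a
    homoscedastic-uncertainty-weighted concentration plus reconstruction
    loss, a semi-supervised endmember-guided Siamese autoencoder (ACU-SA)
    with a fixed linear decoder and a shallow normalization CNN, PLS and
    MLP baselines, preprocessing of raw hyperspectral cube triplets
    (dark subtraction, sensitivity correction, spatial binning, sample
    masking), a seeded synthetic phantom and pig-brain-homogenate
    simulator, and split-by-sample evaluation metrics (Pearson R,
    calibrated RMSE, reconstruction MSE, false-positive rate,
    Kolmogorov-Smirnov tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    pracma,
    data.table,
    withr,
    jsonlite,
    yaml,
    EBImage,
    mixOmics,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
biocViews: Software, Spectroscopy, Preprocessing, Regression
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'WavelengthGrid.R'
    'EndmemberLibrary.R'
    'HyperCube.R'
    'RcppExports.R'
    'SpectraSet.R'
    'classical.R'
    'nn-engine.R'
    'acunet.R'
    'synthetic.R'
    'acusa.R'
    'baselines.R'
    'evaluate.R'
    'fluorounmix-package.R'
    'pipeline.R'
    'preprocess.R'
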