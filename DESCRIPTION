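Package: faceMorph
Title: Dissection of Three-Dimensional Facial Morphology from Landmarks and Surface Meshes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative dissection of three-dimensional facial
    morphology. Provides generalized Procrustes alignment of landmark
    configurations without scaling, landmark reproducibility and intraclass
    correlation statistics, a library of landmark and surface phenotypes
    (principal curvatures, Euclidean/Manhattan/geodesic distances via fast
    marching on triangle meshes, Farkas-style proportion indices, angles,
    Heron triangle areas, convex-hull volumes and surface areas),
    global-to-local hierarchical spectral segmentation of the face with
    per-segment principal components retained by parallel analysis, segment
    surface areas and Moran's I spatial autocorrelation, and a population
    statistics layer (Spearman screening with Bonferroni control, PLS-DA
    with VIP variable selection, PERMANOVA, age adjustment). Includes a
    synthetic face-population generator with known regional structure for
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape,
    vegan,
    mixOmics,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, DimensionReduction, Clustering
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dictionary.R'
    'align.R'
    'distances.R'
    'curvature.R'
    'io.R'
    'phenotypes.R'
    'segmentation.R'
    'pipeline.R'
    'template.R'
    'simulate.R'
    'stats.R'
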