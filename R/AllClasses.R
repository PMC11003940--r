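#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SurfaceMesh: a triangulated facial surface
#'
#' Holds vertex coordinates (in mm) and triangular face connectivity for a
#' scanned or synthetic facial surface. Vertex indices are 1-based throughout
#' the package; file readers convert from the on-disk convention (OBJ is
#' 1-based, PLY 0-based).
#'
#' @slot vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot vertexData optional per-vertex scalar attributes (a
#'   \linkS4class{DataFrame} with one row per vertex).
#'
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", vertexData = "DataFrame"),
  prototype(vertices = matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("x", "y", "z"))),
            faces = matrix(integer(0), 0, 3),
            vertexData = S4Vectors::DataFrame()))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns (x, y, z)")
  if (ncol(f) != 3L) return("faces must have 3 columns (triangles only)")
  if (!all(is.finite(v))) return("non-finite vertex coordinate")
  if (nrow(f) > 0L) {
    if (any(f < 1L) || any(f > nrow(v)))
      return(sprintf("face refers to vertex outside 1..%d (first bad face: %d)",
                     nrow(v), which(apply(f, 1L, function(r) any(r < 1L | r > nrow(v))))[1L]))
    rep_v <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(rep_v))
      return(sprintf("face %d has a repeated vertex", which(rep_v)[1L]))
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    len2 <- rowSums((v[e[, 1L], , drop = FALSE] - v[e[, 2L], , drop = FALSE])^2)
    if (any(len2 == 0))
      return("mesh contains a zero-length edge")
  }
  if (nrow(object@vertexData) > 0L && nrow(object@vertexData) != nrow(v))
    return("vertexData must have one row per vertex")
  TRUE
})

#' LandmarkDictionary: the ordered set of named facial landmarks
#'
#' Defines the landmark battery: ordered names, anatomical descriptions and
#' the left/right pairing structure. The default battery
#' (\code{\link{defaultLandmarkDictionary}}) contains 26 Farkas-convention
#' soft-tissue landmarks.
#'
#' @slot names ordered landmark names (unique).
#' @slot description anatomical definition per landmark.
#' @slot side "L", "R" or "mid".
#' @slot pair name of the contralateral landmark, or NA for midline points.
#'
#' @exportClass LandmarkDictionary
setClass("LandmarkDictionary",
  representation(names = "character", description = "character",
                 side = "character", pair = "character"))

setValidity("LandmarkDictionary", function(object) {
  n <- object@names
  if (anyDuplicated(n)) return("landmark names must be unique")
  if (length(object@description) != length(n) ||
      length(object@side) != length(n) || length(object@pair) != length(n))
    return("all slots must have one entry per landmark")
  if (!all(object@side %in% c("L", "R", "mid")))
    return("side must be L, R or mid")
  paired <- !is.na(object@pair)
  if (any(paired)) {
    if (!all(object@pair[paired] %in% n))
      return("pair refers to an unknown landmark")
    idx <- match(object@pair[paired], n)
    back <- object@pair[idx]
    if (any(is.na(back)) || !all(back == n[paired]))
      return("pairing must be symmetric")
  }
  if (any(paired != (object@side %in% c("L", "R"))))
    return("exactly the L/R landmarks must be paired")
  TRUE
})

#' LandmarkSet: one landmarking of one individual
#'
#' 3D coordinates (mm) of the dictionary's landmarks for one individual and
#' one landmarking replicate, stored in dictionary order.
#'
#' @slot coords numeric matrix (landmarks x 3), rownames are landmark names.
#' @slot individual individual identifier.
#' @slot replicate replicate identifier (e.g. "1", "2").
#'
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(coords = "matrix", individual = "character",
                 replicate = "character"),
  prototype(individual = NA_character_, replicate = NA_character_))

setValidity("LandmarkSet", function(object) {
  x <- object@coords
  if (ncol(x) != 3L) return("coords must have 3 columns")
  if (is.null(rownames(x))) return("coords must carry landmark names as rownames")
  if (anyDuplicated(rownames(x))) return("duplicate landmark name")
  if (!all(is.finite(x))) {
    bad <- rownames(x)[!apply(is.finite(x), 1L, all)]
    return(paste("non-finite coordinates for landmark(s):",
                 paste(bad, collapse = ", ")))
  }
  TRUE
})

#' FaceTemplate: procedural face-like template surface
#'
#' A parametric face-like surface patch (half-ellipsoid head with nose ridge,
#' eye depressions and a mouth groove) together with the template vertex ids
#' of the 26 landmarks. Built by \code{\link{buildTemplate}}.
#'
#' @slot mesh the template \linkS4class{SurfaceMesh}.
#' @slot landmarkIndex named integer vector: template vertex id per landmark.
#' @slot dictionary the \linkS4class{LandmarkDictionary} the ids follow.
#' @slot resolution the grid resolution the template was built at.
#'
#' @exportClass FaceTemplate
setClass("FaceTemplate",
  representation(mesh = "SurfaceMesh", landmarkIndex = "integer",
                 dictionary = "LandmarkDictionary", resolution = "numeric"))

setValidity("FaceTemplate", function(object) {
  idx <- object@landmarkIndex
  nv <- nrow(object@mesh@vertices)
  if (length(idx) != length(object@dictionary@names))
    return("one landmark vertex id per dictionary entry required")
  if (anyDuplicated(idx)) return("landmark vertex ids must be distinct")
  if (any(idx < 1L) || any(idx > nv)) return("landmark vertex id out of range")
  if (is.null(names(idx)) || !all(names(idx) == object@dictionary@names))
    return("landmarkIndex names must match dictionary order")
  TRUE
})

#' PopulationModel: generative model for a synthetic face population
#'
#' Describes the population structure a synthetic sample is drawn from:
#' regional mean-shape displacements (including graded north-to-south
#' "gradient" traits), per-individual Gaussian shape variation, per-landmark
#' landmarking noise, linear sex/age drift and the warp bandwidth used to
#' deform the template mesh consistently with the landmarks.
#'
#' @slot regions region labels ordered north to south.
#' @slot regionShift array (landmarks x 3 x regions) of mean displacements (mm).
#' @slot gradientTraits data.frame with columns landmark, axis ("x","y","z"),
#'   delta (mm): traits whose region means are monotone north to south, with
#'   displacement +delta in the northernmost region down to -delta in the
#'   southernmost.
#' @slot sigmaInd SD of individual shape variation per coordinate (mm).
#' @slot sigmaMeas landmarking noise SD (mm); scalar or one value per landmark.
#' @slot sexEffect matrix (landmarks x 3): displacement added for males (mm).
#' @slot ageEffect matrix (landmarks x 3): displacement per year of age,
#'   centred at the population mean age (mm/yr).
#' @slot bandwidth Gaussian RBF warp bandwidth (mm).
#'
#' @exportClass PopulationModel
setClass("PopulationModel",
  representation(regions = "character", regionShift = "array",
                 gradientTraits = "data.frame", sigmaInd = "numeric",
                 sigmaMeas = "numeric", sexEffect = "matrix",
                 ageEffect = "matrix", bandwidth = "numeric"))

setValidity("PopulationModel", function(object) {
  if (object@sigmaInd < 0 || any(object@sigmaMeas < 0))
    return("noise SDs must be >= 0")
  if (object@bandwidth <= 0) return("warp bandwidth must be > 0")
  d <- dim(object@regionShift)
  if (length(d) != 3L || d[3L] != length(object@regions))
    return("regionShift must be landmarks x 3 x regions")
  gt <- object@gradientTraits
  if (nrow(gt) > 0L) {
    if (!all(c("landmark", "axis", "delta") %in% names(gt)))
      return("gradientTraits needs columns landmark, axis, delta")
    if (!all(gt$axis %in% c("x", "y", "z"))) return("gradient axis must be x/y/z")
  }
  TRUE
})

#' FacePopulation: a sample of individuals with meshes and landmark replicates
#'
#' Per-individual facial surface plus two landmarking replicates, with region,
#' sex and age labels. Produced by \code{\link{simulatePopulation}}; external
#' data can be assembled with the constructor directly.
#'
#' @slot template the \linkS4class{FaceTemplate} meshes correspond to (vertex
#'   order), or a zero-vertex template for external data without dense
#'   correspondence.
#' @slot meshes list of \linkS4class{SurfaceMesh}, one per individual.
#' @slot landmarksA first-replicate \linkS4class{LandmarkSet} per individual.
#' @slot landmarksB second-replicate \linkS4class{LandmarkSet} per individual.
#' @slot trueLandmarks noise-free landmark sets (synthetic data only; empty
#'   list otherwise).
#' @slot sampleData \linkS4class{DataFrame} with columns id, region, sex, age.
#'
#' @exportClass FacePopulation
setClass("FacePopulation",
  representation(template = "FaceTemplate", meshes = "list",
                 landmarksA = "list", landmarksB = "list",
                 trueLandmarks = "list", sampleData = "DataFrame"))

setValidity("FacePopulation", function(object) {
  n <- nrow(object@sampleData)
  if (!all(c("id", "region", "sex", "age") %in% colnames(object@sampleData)))
    return("sampleData needs columns id, region, sex, age")
  if (length(object@landmarksA) != n || length(object@landmarksB) != n)
    return("exactly two landmark replicates per individual required")
  if (length(object@meshes) > 0L && length(object@meshes) != n)
    return("meshes must be empty or one per individual")
  TRUE
})

#' ProcrustesAlignment: result of generalized Procrustes analysis
#'
#' Aligned landmark configurations (translation and rotation removed, scale
#' deliberately preserved), the consensus shape, the fitted rigid transforms
#' and the convergence record. Produced by \code{\link{gpa}}.
#'
#' @slot aligned array (landmarks x 3 x individuals) of aligned coordinates.
#' @slot consensus consensus (mean) shape, landmarks x 3.
#' @slot rotations list of 3x3 rotation matrices (det +1) applied per set.
#' @slot translations matrix (individuals x 3) of removed centroids.
#' @slot objective per-iteration sum of squared distances to the consensus.
#' @slot iterations iterations used.
#'
#' @exportClass ProcrustesAlignment
setClass("ProcrustesAlignment",
  representation(aligned = "array", consensus = "matrix", rotations = "list",
                 translations = "matrix", objective = "numeric",
                 iterations = "integer"))

#' FacePhenotypes: individuals-by-phenotypes container
#'
#' A \linkS4class{SummarizedExperiment} with phenotypes as rows and
#' individuals as columns. \code{rowData} carries the phenotype category (one
#' of the 15 categories of the phenotype library) and units; \code{colData}
#' carries region, sex and age.
#'
#' @exportClass FacePhenotypes
setClass("FacePhenotypes", contains = "SummarizedExperiment")

#' The 15 phenotype categories of the facial phenotype library
#'
#' Category tags used in \code{rowData(x)$category} of a
#' \linkS4class{FacePhenotypes} object: point coordinates, curvatures, the
#' three distance families, proportion indices, angles, triangle areas,
#' volumes and surface areas from landmarks, and per-segment principal
#' components, surface area and Moran's I of z / mean curvature / Gaussian
#' curvature from the facial segmentation.
#'
#' @export
PHENOTYPE_CATEGORIES <- c(
  "Point", "Curvature", "Euclidean", "Manhattan", "Geodesic", "Index",
  "Angle", "Triangle_area", "Volume", "Surface_area",
  "Module_PCs", "Module_surf_area", "Module_mor_z", "Module_mor_mea",
  "Module_mor_gau")

setValidity("FacePhenotypes", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("category", "units") %in% colnames(rd)))
    return("rowData must carry 'category' and 'units'")
  if (!all(rd$category %in% PHENOTYPE_CATEGORIES))
    return(paste("unknown phenotype category:",
                 paste(setdiff(unique(rd$category), PHENOTYPE_CATEGORIES),
                       collapse = ", ")))
  TRUE
})

#' SegmentHierarchy: global-to-local facial segmentation
#'
#' Recursive binary partition of the template vertices into a hierarchy of
#' facial segments: level 1 is the whole face, each subsequent level splits
#' every segment in two, giving 2^L - 1 segments over L levels (127 at the
#' default 7) unless a minimum-size guard stops a branch.
#'
#' @slot nLevels number of levels L.
#' @slot table data.frame with columns id, level, parent, size.
#' @slot members list (indexed by segment id as character) of template vertex
#'   ids belonging to each segment.
#' @slot assignment integer matrix (vertices x levels): segment id of each
#'   vertex at each level.
#'
#' @exportClass SegmentHierarchy
setClass("SegmentHierarchy",
  representation(nLevels = "integer", table = "data.frame", members = "list",
                 assignment = "matrix"))

setValidity("SegmentHierarchy", function(object) {
  tab <- object@table
  for (i in seq_len(nrow(tab))) {
    if (tab$level[i] > 1L) {
      par <- object@members[[as.character(tab$parent[i])]]
      mem <- object@members[[as.character(tab$id[i])]]
      if (!all(mem %in% par)) return("child segment not contained in parent")
    }
  }
  TRUE
})

#' PlsdaModel: partial least squares discriminant analysis fit
#'
#' NIPALS PLS2 regression of one-hot group membership on autoscaled
#' phenotypes, with per-variable VIP (variable importance in projection)
#' scores, cumulative R2X/R2Y and cross-validated Q2. Produced by
#' \code{\link{plsda}}.
#'
#' @slot ncomp number of retained components.
#' @slot weights X-weight matrix W (variables x components).
#' @slot loadings X-loading matrix P (variables x components).
#' @slot scores score matrix T (samples x components).
#' @slot yloadings Y-loading matrix Q (groups x components).
#' @slot vip named per-variable VIP scores.
#' @slot R2X,R2Y,Q2 cumulative explained variance in X and Y, and
#'   cross-validated predictive Q2.
#' @slot center,scale the autoscaling applied to X.
#' @slot groups group level labels.
#'
#' @exportClass PlsdaModel
setClass("PlsdaModel",
  representation(ncomp = "integer", weights = "matrix", loadings = "matrix",
                 scores = "matrix", yloadings = "matrix", vip = "numeric",
                 R2X = "numeric", R2Y = "numeric", Q2 = "numeric",
                 center = "numeric", scale = "numeric", groups = "character"))
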