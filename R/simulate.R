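#' @include AllClasses.R template.R
NULL

#' Construct a population model for synthetic face simulation
#'
#' The model describes three regional groups ordered north to south with
#' graded mean-shape differences on a small set of "gradient" landmark
#' coordinates, individual Gaussian shape variation, per-landmark
#' landmarking noise (two replicates), small linear sex and age drifts, and
#' the bandwidth of the mesh warp tying surfaces to landmarks.
#'
#' Gradient traits receive a mean displacement of \code{+delta} in the
#' northernmost region, grading linearly to \code{-delta} in the
#' southernmost, so their region means are strictly monotone by
#' construction. The default battery covers 8 of the 78 landmark
#' coordinates (10 percent), balanced across axes and sides.
#'
#' @param regions region labels, ordered north to south.
#' @param gradientTraits data.frame(landmark, axis, delta) of graded traits;
#'   \code{delta} in mm.
#' @param sigmaInd SD (mm) of individual shape variation per coordinate.
#' @param sigmaMeas landmarking noise SD (mm); scalar, or a named vector with
#'   one value per landmark to mimic landmark-specific reproducibility
#'   (lateral points such as zygion are far noisier in practice).
#' @param sexEffect,ageEffect 26 x 3 matrices of mean displacement for males
#'   and per year of age (centred); defaults are small drifts so that age
#'   adjustment has signal to remove; pass zero matrices to switch off.
#' @param bandwidth Gaussian RBF warp bandwidth (mm).
#' @param dictionary the landmark dictionary the matrices refer to.
#' @return a \linkS4class{PopulationModel}.
#' @export
populationModel <- function(regions = c("north", "central", "south"),
                            gradientTraits = defaultGradientTraits(),
                            sigmaInd = 1.0, sigmaMeas = 0.5,
                            sexEffect = NULL, ageEffect = NULL,
                            bandwidth = 30,
                            dictionary = defaultLandmarkDictionary()) {
  nl <- length(landmarkNames(dictionary))
  zero <- matrix(0, nl, 3L, dimnames = list(landmarkNames(dictionary),
                                            c("x", "y", "z")))
  if (is.null(sexEffect)) {
    sexEffect <- zero
    sexEffect["pogonion", "y"] <- -1.0   # males: slightly longer lower face
    sexEffect["gonion_L", "x"] <- -0.8   # and wider jaw
    sexEffect["gonion_R", "x"] <- 0.8
  }
  if (is.null(ageEffect)) {
    ageEffect <- zero
    ageEffect["cheilion_L", "y"] <- -0.02  # mild soft-tissue descent per year
    ageEffect["cheilion_R", "y"] <- -0.02
  }
  shift <- array(0, dim = c(nl, 3L, length(regions)),
                 dimnames = list(landmarkNames(dictionary), c("x", "y", "z"),
                                 regions))
  new("PopulationModel", regions = regions, regionShift = shift,
      gradientTraits = gradientTraits, sigmaInd = sigmaInd,
      sigmaMeas = sigmaMeas, sexEffect = sexEffect, ageEffect = ageEffect,
      bandwidth = bandwidth)
}

#' Default graded north-to-south traits
#'
#' Eight landmark coordinates (10 percent of the 78) carrying a monotone
#' regional gradient of 1.0-1.5 mm, balanced so that per-axis centroid
#' leakage through Procrustes centring is negligible: nose projection and
#' height, face height, and bilateral face/nose widths.
#'
#' @return data.frame with columns landmark, axis, delta.
#' @export
defaultGradientTraits <- function() {
  data.frame(
    landmark = c("pronasale", "subnasale", "nasion", "gnathion",
                 "zygion_L", "zygion_R", "alare_L", "alare_R"),
    axis = c("z", "z", "y", "y", "x", "x", "x", "x"),
    delta = c(1.5, -1.2, 1.5, -1.5, -1.5, 1.5, -1.0, 1.0),
    stringsAsFactors = FALSE)
}

# Mean landmark displacement (26 x 3) for one region index.
.region_displacement <- function(model, dict, r) {
  nl <- length(landmarkNames(dict))
  disp <- model@regionShift[, , r]
  gt <- model@gradientTraits
  if (nrow(gt) > 0L) {
    nr <- length(model@regions)
    grade <- if (nr > 1L) seq(1, -1, length.out = nr)[r] else 0
    for (i in seq_len(nrow(gt))) {
      li <- match(gt$landmark[i], landmarkNames(dict))
      ai <- match(gt$axis[i], c("x", "y", "z"))
      if (is.na(li)) stop("gradient trait refers to unknown landmark: ",
                          gt$landmark[i])
      disp[li, ai] <- disp[li, ai] + gt$delta[i] * grade
    }
  }
  disp
}

#' Warp the template mesh to interpolate target landmarks
#'
#' Gaussian radial-basis-function interpolation: the warp displaces each
#' template landmark vertex exactly onto its target, with the displacement
#' field decaying smoothly with distance at the model bandwidth. Vertices at
#' 3 bandwidths from a moved landmark displace by about 1 percent of the
#' landmark's displacement.
#'
#' @param template a \linkS4class{FaceTemplate}.
#' @param targetLandmarks a \linkS4class{LandmarkSet} in dictionary order.
#' @param bandwidth kernel bandwidth (mm).
#' @return a warped \linkS4class{SurfaceMesh} in template vertex order.
#' @export
warpMesh <- function(template, targetLandmarks, bandwidth = 30) {
  stopifnot(is(template, "FaceTemplate"), is(targetLandmarks, "LandmarkSet"))
  tgt <- coords(targetLandmarks)
  if (!all(is.finite(tgt))) stop("target landmarks must be finite")
  dtgt <- as.matrix(stats::dist(tgt))
  if (any(dtgt[upper.tri(dtgt)] == 0))
    stop("degenerate target: coincident landmarks")
  src <- coords(templateLandmarks(template))
  delta <- tgt[rownames(src), , drop = FALSE] - src
  K <- exp(-as.matrix(stats::dist(src))^2 / (2 * bandwidth^2))
  alpha <- solve(K, delta)
  v <- template@mesh@vertices
  d2 <- outer(rowSums(v^2), rowSums(src^2), "+") - 2 * v %*% t(src)
  Kv <- exp(-pmax(d2, 0) / (2 * bandwidth^2))
  SurfaceMesh(v + Kv %*% alpha, template@mesh@faces)
}

#' Simulate a face population with known regional structure
#'
#' Draws \code{nPerRegion} individuals per region. Each individual's true
#' landmarks are the template landmarks plus the region's mean displacement
#' (including graded traits), sex and age drift, and i.i.d. Gaussian
#' individual variation; the mesh is warped to the true landmarks; each of
#' the two landmarking replicates adds independent per-landmark measurement
#' noise. Fully reproducible from the seed.
#'
#' @param template a \linkS4class{FaceTemplate}.
#' @param model a \linkS4class{PopulationModel}.
#' @param nPerRegion individuals per region (>= 1).
#' @param seed integer RNG seed.
#' @param warpMeshes set FALSE to skip mesh warping (landmark-only studies).
#' @return a \linkS4class{FacePopulation}.
#' @examples
#' tpl <- buildTemplate()
#' pop <- simulatePopulation(tpl, populationModel(), nPerRegion = 3,
#'                           seed = 1, warpMeshes = FALSE)
#' pop
#' @export
simulatePopulation <- function(template, model = populationModel(),
                               nPerRegion = 100L, seed = 1L,
                               warpMeshes = TRUE) {
  stopifnot(is(template, "FaceTemplate"), is(model, "PopulationModel"))
  if (nPerRegion < 1L) stop("nPerRegion must be >= 1")
  dict <- template@dictionary
  nl <- length(landmarkNames(dict))
  sm <- model@sigmaMeas
  if (length(sm) == 1L) sm <- rep(sm, nl)
  if (length(sm) != nl) stop("sigmaMeas must be scalar or one value per landmark")
  tpl <- coords(templateLandmarks(template))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  nR <- length(model@regions)
  n <- nR * nPerRegion
  region <- rep(model@regions, each = nPerRegion)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 48.9, 12.7)), 17), 83)
  ids <- sprintf("ind%04d", seq_len(n))
  meshes <- vector("list", if (warpMeshes) n else 0L)
  lmsA <- lmsB <- truth <- vector("list", n)
  age_c <- age - mean(age)
  for (i in seq_len(n)) {
    r <- match(region[i], model@regions)
    true <- tpl + .region_displacement(model, dict, r) +
      (sex[i] == "M") * model@sexEffect + age_c[i] * model@ageEffect +
      matrix(stats::rnorm(nl * 3L, 0, model@sigmaInd), nl, 3L)
    rownames(true) <- rownames(tpl)
    truth[[i]] <- LandmarkSet(true, individual = ids[i])
    if (warpMeshes)
      meshes[[i]] <- warpMesh(template, truth[[i]], model@bandwidth)
    lmsA[[i]] <- LandmarkSet(true + matrix(stats::rnorm(nl * 3L, 0, rep(sm, 3L)),
                                           nl, 3L),
                             individual = ids[i], replicate = "1")
    lmsB[[i]] <- LandmarkSet(true + matrix(stats::rnorm(nl * 3L, 0, rep(sm, 3L)),
                                           nl, 3L),
                             individual = ids[i], replicate = "2")
  }
  new("FacePopulation", template = template, meshes = meshes,
      landmarksA = lmsA, landmarksB = lmsB, trueLandmarks = truth,
      sampleData = S4Vectors::DataFrame(id = ids, region = region, sex = sex,
                                        age = age, row.names = ids))
}
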