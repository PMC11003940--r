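#' @include AllClasses.R
NULL

# The default battery: 26 Farkas-convention soft-tissue landmarks (10 midline,
# 8 bilateral pairs). Supplementary landmark lists vary between studies; this
# battery is a documented, overridable default, not a claim about any
# particular cohort's exact set.
.default_landmarks <- data.frame(
  name = c("glabella", "nasion", "pronasale", "subnasale",
           "labiale_superius", "stomion", "labiale_inferius", "sublabiale",
           "pogonion", "gnathion",
           "endocanthion_L", "endocanthion_R",
           "exocanthion_L", "exocanthion_R",
           "zygion_L", "zygion_R",
           "alare_L", "alare_R",
           "subalare_L", "subalare_R",
           "cheilion_L", "cheilion_R",
           "gonion_L", "gonion_R",
           "tragion_L", "tragion_R"),
  description = c(
    "most prominent midline point between the eyebrows",
    "deepest point of the nasal root in the midline",
    "most protruded point of the nasal tip",
    "junction of the columella and the upper lip in the midline",
    "midpoint of the vermilion border of the upper lip",
    "midpoint of the labial fissure",
    "midpoint of the vermilion border of the lower lip",
    "deepest midline point of the mentolabial sulcus",
    "most anterior midline point of the chin",
    "lowest midline point of the chin",
    "inner commissure of the left eye fissure",
    "inner commissure of the right eye fissure",
    "outer commissure of the left eye fissure",
    "outer commissure of the right eye fissure",
    "most lateral point of the left zygomatic arch",
    "most lateral point of the right zygomatic arch",
    "most lateral point of the left alar contour",
    "most lateral point of the right alar contour",
    "lower attachment of the left nasal ala to the lip",
    "lower attachment of the right nasal ala to the lip",
    "left corner of the mouth",
    "right corner of the mouth",
    "most lateral point of the left mandibular angle",
    "most lateral point of the right mandibular angle",
    "notch above the tragus of the left ear",
    "notch above the tragus of the right ear"),
  side = c(rep("mid", 10L), rep(c("L", "R"), 8L)),
  stringsAsFactors = FALSE)
.default_landmarks$pair <- ifelse(
  .default_landmarks$side == "mid", NA_character_,
  ifelse(.default_landmarks$side == "L",
         sub("_L$", "_R", .default_landmarks$name),
         sub("_R$", "_L", .default_landmarks$name)))

#' Default 26-landmark facial dictionary
#'
#' A Farkas-style battery of 26 soft-tissue landmarks: 10 midline points
#' (glabella, nasion, pronasale, subnasale, labiale superius/inferius,
#' stomion, sublabiale, pogonion, gnathion) and 8 bilateral pairs
#' (endocanthion, exocanthion, zygion, alare, subalare, cheilion, gonion,
#' tragion). Shipped as a documented, overridable default.
#'
#' @return a \linkS4class{LandmarkDictionary}.
#' @examples
#' d <- defaultLandmarkDictionary()
#' landmarkNames(d)
#' @export
defaultLandmarkDictionary <- function() {
  new("LandmarkDictionary",
      names = .default_landmarks$name,
      description = .default_landmarks$description,
      side = .default_landmarks$side,
      pair = .default_landmarks$pair)
}

#' Construct a LandmarkSet
#'
#' @param coords numeric matrix (landmarks x 3) with landmark names as
#'   rownames, in mm.
#' @param individual,replicate identifiers.
#' @param dictionary optional \linkS4class{LandmarkDictionary}; when given,
#'   rows are reordered to dictionary order and completeness is checked.
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(coords, individual = NA_character_,
                        replicate = NA_character_, dictionary = NULL) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(dictionary)) {
    want <- landmarkNames(dictionary)
    have <- rownames(coords)
    if (anyDuplicated(have))
      stop("duplicate landmark row(s): ",
           paste(unique(have[duplicated(have)]), collapse = ", "))
    missing <- setdiff(want, have)
    if (length(missing))
      stop("missing landmark(s): ", paste(missing, collapse = ", "))
    unknown <- setdiff(have, want)
    if (length(unknown))
      stop("unknown landmark(s): ", paste(unknown, collapse = ", "))
    coords <- coords[want, , drop = FALSE]
  }
  new("LandmarkSet", coords = coords,
      individual = as.character(individual), replicate = as.character(replicate))
}

#' Construct a SurfaceMesh
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param vertexData optional per-vertex attributes.
#' @return a \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces, vertexData = S4Vectors::DataFrame()) {
  vertices <- as.matrix(vertices)
  colnames(vertices) <- c("x", "y", "z")
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  new("SurfaceMesh", vertices = vertices, faces = faces, vertexData = vertexData)
}
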