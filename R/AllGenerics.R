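#' @include AllClasses.R
NULL

#' Accessors for mesh, landmark and segmentation objects
#'
#' \code{vertices} and \code{faces} return the coordinate and connectivity
#' matrices of a \linkS4class{SurfaceMesh}; \code{coords} the landmark
#' coordinate matrix of a \linkS4class{LandmarkSet}; \code{landmarkNames} the
#' ordered names of a \linkS4class{LandmarkDictionary};
#' \code{consensus} the consensus shape of a
#' \linkS4class{ProcrustesAlignment}; \code{alignedCoords} its aligned
#' configurations; \code{segmentMembers} the template-vertex ids of one
#' segment of a \linkS4class{SegmentHierarchy}; \code{segmentTable} its
#' segment table; \code{vip} the VIP scores of a \linkS4class{PlsdaModel}.
#'
#' @param x the object.
#' @param id segment id.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("landmarkNames", function(x) standardGeneric("landmarkNames"))
#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @rdname accessors
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))
#' @rdname accessors
#' @export
setGeneric("segmentMembers", function(x, id) standardGeneric("segmentMembers"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("vip", function(x) standardGeneric("vip"))

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("vertices", "FaceTemplate", function(x) x@mesh@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "FaceTemplate", function(x) x@mesh@faces)
#' @rdname accessors
#' @export
setMethod("coords", "LandmarkSet", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("landmarkNames", "LandmarkDictionary", function(x) x@names)
#' @rdname accessors
#' @export
setMethod("landmarkNames", "LandmarkSet", function(x) rownames(x@coords))
#' @rdname accessors
#' @export
setMethod("consensus", "ProcrustesAlignment", function(x) x@consensus)
#' @rdname accessors
#' @export
setMethod("alignedCoords", "ProcrustesAlignment", function(x) x@aligned)
#' @rdname accessors
#' @export
setMethod("segmentMembers", "SegmentHierarchy",
          function(x, id) x@members[[as.character(id)]])
#' @rdname accessors
#' @export
setMethod("segmentTable", "SegmentHierarchy", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("vip", "PlsdaModel", function(x) x@vip)

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices)) {
    rng <- apply(object@vertices, 2L, range)
    cat(sprintf("  bbox (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet: %d landmarks, individual %s, replicate %s\n",
              nrow(object@coords), object@individual, object@replicate))
})

setMethod("show", "LandmarkDictionary", function(object) {
  cat(sprintf("LandmarkDictionary: %d landmarks (%d bilateral pairs)\n",
              length(object@names), sum(object@side == "L")))
  cat(" ", paste(object@names, collapse = ", "), "\n")
})

setMethod("show", "FaceTemplate", function(object) {
  cat(sprintf("FaceTemplate: %d vertices, %d faces, %d landmarks (resolution %g)\n",
              nrow(object@mesh@vertices), nrow(object@mesh@faces),
              length(object@landmarkIndex), object@resolution))
})

setMethod("show", "FacePopulation", function(object) {
  sd <- object@sampleData
  cat(sprintf("FacePopulation: %d individuals (%s), %s\n", nrow(sd),
              paste(sprintf("%s n=%d", names(table(sd$region)), table(sd$region)),
                    collapse = ", "),
              if (length(object@meshes)) "with meshes" else "landmarks only"))
})

setMethod("show", "ProcrustesAlignment", function(object) {
  cat(sprintf(paste0("ProcrustesAlignment: %d configurations x %d landmarks, ",
                     "%d iterations, final SS %.4g\n"),
              dim(object@aligned)[3L], dim(object@aligned)[1L],
              object@iterations, utils::tail(object@objective, 1L)))
})

setMethod("show", "SegmentHierarchy", function(object) {
  cat(sprintf("SegmentHierarchy: %d levels, %d segments, %d vertices\n",
              object@nLevels, nrow(object@table), nrow(object@assignment)))
})

setMethod("show", "PlsdaModel", function(object) {
  cat(sprintf("PlsdaModel: %d components over %d variables, groups: %s\n",
              object@ncomp, nrow(object@weights),
              paste(object@groups, collapse = ", ")))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n",
              utils::tail(object@R2X, 1L), utils::tail(object@R2Y, 1L),
              utils::tail(object@Q2, 1L)))
})
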