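#' @include AllClasses.R distances.R
NULL

#' Radius-limited vertex neighbourhoods
#'
#' For each requested vertex, the set of vertices reachable along mesh edges
#' that lie within a Euclidean radius of it (the vertex itself excluded).
#' Used as the support of the local quadric fits in
#' \code{\link{vertexCurvatures}}.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param radius neighbourhood radius in mm.
#' @param which vertex ids to build neighbourhoods for (default all).
#' @return list of integer vectors, indexed like \code{which}.
#' @export
meshNeighborhoods <- function(mesh, radius = 10, which = NULL) {
  v <- vertices(mesh); f <- faces(mesh)
  if (is.null(which)) which <- seq_len(nrow(v))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2L], e[, 1L])
  adj <- lapply(adj, unique)
  full <- vector("list", nrow(v))
  full[as.integer(names(adj))] <- adj
  r2 <- radius^2
  lapply(which, function(i) {
    seen <- i
    frontier <- i
    repeat {
      nxt <- unique(unlist(full[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      d2 <- (v[nxt, 1L] - v[i, 1L])^2 + (v[nxt, 2L] - v[i, 2L])^2 +
        (v[nxt, 3L] - v[i, 3L])^2
      nxt <- nxt[d2 <= r2]
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    setdiff(seen, i)
  })
}

#' Principal curvatures at mesh vertices
#'
#' Fits a quadric (Monge patch) to each vertex's neighbourhood in its
#' tangent frame and reports the principal curvatures, ordered by magnitude
#' (\code{kmax} is the larger in absolute value), together with mean
#' curvature MC = (kmax + kmin)/2 and Gaussian curvature GC = kmax * kmin.
#' Normals point away from the mesh centroid, so convex regions (the nose
#' tip) have positive MC; a sphere of radius r gives MC = 1/r, GC = 1/r^2.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param neighborhoods as from \code{\link{meshNeighborhoods}} (one entry
#'   per requested vertex).
#' @param which vertex ids matching \code{neighborhoods} (default all).
#' @return data.frame with columns vertex, kmax, kmin, MC (1/mm), GC (1/mm^2).
#' @export
vertexCurvatures <- function(mesh, neighborhoods = NULL, which = NULL) {
  v <- vertices(mesh)
  if (is.null(which)) which <- seq_len(nrow(v))
  if (is.null(neighborhoods))
    neighborhoods <- meshNeighborhoods(mesh, 10, which)
  full <- vector("list", nrow(v))
  full[which] <- neighborhoods
  res <- .mesh_curvature_cpp(v, faces(mesh), full, as.integer(which))
  data.frame(vertex = which, kmax = res$kmax, kmin = res$kmin,
             MC = (res$kmax + res$kmin) / 2, GC = res$kmax * res$kmin)
}

#' Curvature profiles at the 26 landmarks
#'
#' Snaps each landmark to its nearest mesh vertex and estimates its
#' principal, mean and Gaussian curvatures from a quadric fit over the
#' surrounding surface patch.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param lms a \linkS4class{LandmarkSet} on (or near) the surface.
#' @param radius quadric-fit neighbourhood radius (mm, default 10).
#' @param snapTol landmark snap tolerance (mm, default 2).
#' @return data.frame with one row per landmark: landmark, kmax, kmin, MC, GC.
#' @export
landmarkCurvatures <- function(mesh, lms, radius = 10, snapTol = 2) {
  idx <- .snap_landmarks(mesh, lms, snapTol)
  nb <- meshNeighborhoods(mesh, radius, idx)
  few <- lengths(nb) < 6L
  if (any(few))
    stop("fewer than 6 neighbours within ", radius, " mm of landmark(s): ",
         paste(names(idx)[few], collapse = ", "))
  out <- vertexCurvatures(mesh, nb, idx)
  data.frame(landmark = names(idx), out[, c("kmax", "kmin", "MC", "GC")],
             row.names = NULL)
}
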