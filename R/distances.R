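#' @include AllClasses.R
#' @useDynLib faceMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.pair_index <- function(nms) {
  p <- length(nms)
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  list(i = ij[, 1L], j = ij[, 2L],
       name = paste(nms[ij[, 1L]], nms[ij[, 2L]], sep = "-"))
}

#' Pairwise Euclidean distances between landmarks
#'
#' All C(26,2) = 325 straight-line distances for the default battery.
#'
#' @param lms a \linkS4class{LandmarkSet} (for Manhattan distances, one in
#'   the GPA consensus frame).
#' @return named numeric vector, one value per unordered landmark pair (mm).
#' @export
euclideanDistances <- function(lms) {
  x <- coords(lms)
  pr <- .pair_index(rownames(x))
  d <- sqrt(rowSums((x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE])^2))
  names(d) <- pr$name
  d
}

#' Pairwise Manhattan (city-block) distances between landmarks
#'
#' Sum of absolute per-axis differences. Axis-dependent: unlike the other
#' phenotypes this measure is not invariant to rotation, so it must be
#' computed on configurations expressed in the GPA consensus frame.
#'
#' @inheritParams euclideanDistances
#' @return named numeric vector (mm), one value per pair.
#' @export
manhattanDistances <- function(lms) {
  x <- coords(lms)
  pr <- .pair_index(rownames(x))
  d <- rowSums(abs(x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE]))
  names(d) <- pr$name
  d
}

.snap_landmarks <- function(mesh, lms, tol = 2) {
  v <- vertices(mesh)
  x <- coords(lms)
  idx <- integer(nrow(x)); names(idx) <- rownames(x)
  for (i in seq_len(nrow(x))) {
    d2 <- (v[, 1L] - x[i, 1L])^2 + (v[, 2L] - x[i, 2L])^2 +
      (v[, 3L] - x[i, 3L])^2
    idx[i] <- which.min(d2)
    if (sqrt(d2[idx[i]]) > tol)
      stop(sprintf("landmark %s is %.2f mm from the surface (snap tolerance %g mm)",
                   rownames(x)[i], sqrt(d2[idx[i]]), tol))
  }
  idx
}

#' Pairwise on-surface geodesic distances between landmarks
#'
#' Shortest-path lengths constrained to the triangulated surface, computed
#' by fast marching (unit-speed Eikonal solve) from each landmark's nearest
#' mesh vertex; the 26 single-source solves give all 325 pairs, symmetrised
#' by averaging the two directions. Every geodesic is at least as long as
#' the corresponding Euclidean chord.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param lms a \linkS4class{LandmarkSet}; each landmark must lie within
#'   \code{snapTol} of a mesh vertex.
#' @param snapTol landmark-to-surface snap tolerance (mm, default 2).
#' @param nSweeps post-marching relaxation sweeps (default 2).
#' @return named numeric vector (mm), one value per pair.
#' @export
geodesicDistances <- function(mesh, lms, snapTol = 2, nSweeps = 2L) {
  idx <- .snap_landmarks(mesh, lms, snapTol)
  p <- length(idx)
  D <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    d <- .fmm_geodesic_cpp(vertices(mesh), faces(mesh), idx[i], nSweeps)
    D[i, ] <- d[idx]
  }
  if (any(!is.finite(D)))
    stop("mesh is disconnected between landmarks: ",
         paste(unique(rownames(coords(lms))[which(!is.finite(D), arr.ind = TRUE)[, 2L]]),
               collapse = ", "))
  D <- (D + t(D)) / 2
  pr <- .pair_index(rownames(coords(lms)))
  d <- D[cbind(pr$i, pr$j)]
  names(d) <- pr$name
  d
}

#' Geodesic distance field from source vertices
#'
#' Lower-level access to the fast-marching solver: distance from the given
#' source vertex ids to every vertex of the mesh.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param sources integer vertex ids (1-based).
#' @param nSweeps post-marching relaxation sweeps.
#' @return numeric vector of distances (mm), one per vertex; \code{Inf} for
#'   vertices not connected to any source.
#' @export
geodesicField <- function(mesh, sources, nSweeps = 2L) {
  .fmm_geodesic_cpp(vertices(mesh), faces(mesh), as.integer(sources),
                    as.integer(nSweeps))
}
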