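#' @include AllClasses.R align.R
NULL

#' Per-individual dense displacement fields
#'
#' Vertex-wise displacement of each individual's surface from the template,
#' expressed in the GPA consensus frame: the landmark GPA transform of each
#' individual (centring + rotation) is applied to its whole mesh, the
#' template is rigidly aligned to the same consensus, and the fields are the
#' vertex differences. Requires meshes in template correspondence (same
#' vertex count and order), which synthetic populations have by
#' construction; externally registered data must supply correspondence.
#'
#' @param population a \linkS4class{FacePopulation} with meshes.
#' @param alignment optional precomputed \linkS4class{ProcrustesAlignment} of
#'   the replicate-averaged landmarks.
#' @return array (vertices x 3 x individuals) of displacements (mm).
#' @export
displacementField <- function(population, alignment = NULL) {
  stopifnot(is(population, "FacePopulation"))
  tpl <- population@template
  nvt <- nrow(tpl@mesh@vertices)
  if (!length(population@meshes))
    stop("population carries no meshes")
  bad <- which(vapply(population@meshes, function(m) nrow(m@vertices), 0L) != nvt)
  if (length(bad))
    stop("mesh ", bad[1L], " is not in template correspondence (",
         nrow(population@meshes[[bad[1L]]]@vertices), " vs ", nvt,
         " vertices); register externally first")
  avg <- mapply(averageReplicates, population@landmarksA,
                population@landmarksB, SIMPLIFY = FALSE)
  if (is.null(alignment)) alignment <- gpa(avg)
  n <- length(avg)
  # template into the consensus frame
  tlm <- coords(templateLandmarks(tpl))
  tcent <- colMeans(tlm)
  Rt <- .kabsch(sweep(tlm, 2L, tcent), alignment@consensus)
  tv <- sweep(tpl@mesh@vertices, 2L, tcent) %*% Rt
  fields <- array(NA_real_, c(nvt, 3L, n),
                  dimnames = list(NULL, c("x", "y", "z"),
                                  dimnames(alignment@aligned)[[3L]]))
  for (i in seq_len(n)) {
    vi <- sweep(population@meshes[[i]]@vertices, 2L,
                alignment@translations[i, ]) %*% alignment@rotations[[i]]
    fields[, , i] <- vi - tv
  }
  fields
}

#' Vertex-pair similarity of shape covariation
#'
#' RV coefficient between the 3D displacement matrices of every pair of
#' template vertices across individuals:
#' RV(i, j) = ||Xi'Xj||_F^2 / (||Xi'Xi||_F ||Xj'Xj||_F), values in [0, 1].
#' Vertices that covary through the same latent deformation score near 1;
#' independent vertices near 0. Zero-variance vertices get similarity 0
#' (with a warning).
#'
#' @param fields displacement array from \code{\link{displacementField}}
#'   (vertices x 3 x individuals, >= 10 individuals).
#' @param chunk vertices per block in the blocked cross-product (memory
#'   control).
#' @return symmetric similarity matrix (vertices x vertices).
#' @export
vertexSimilarity <- function(fields, chunk = 256L) {
  p <- dim(fields)[1L]; n <- dim(fields)[3L]
  if (n < 10L) stop("need >= 10 individuals for covariation similarity")
  # A: individuals x (3 per-vertex columns), column-centred
  A <- matrix(aperm(fields, c(3L, 2L, 1L)), nrow = n)  # cols: (x,y,z) per vertex
  A <- scale(A, scale = FALSE)
  grp <- rep(seq_len(p), each = 3L)
  S <- matrix(NA_real_, p, p)
  for (start in seq(1L, p, by = chunk)) {
    iv <- start:min(start + chunk - 1L, p)
    cols <- which(grp %in% iv)
    Ci <- crossprod(A[, cols, drop = FALSE], A)      # 3c x 3p
    M <- Ci^2
    s1 <- rowsum(M, rep(iv, each = 3L))              # c x 3p
    S[iv, ] <- t(rowsum(t(s1), grp))                 # c x p
  }
  den <- sqrt(diag(S))
  zero <- den == 0
  if (any(zero)) warning(sum(zero), " zero-variance vertices: similarity set to 0")
  den[zero] <- 1
  S <- S / outer(den, den)
  S[zero, ] <- 0; S[, zero] <- 0
  diag(S)[!zero] <- 1
  S
}

# Fiedler vector of the symmetric normalized Laplacian of W restricted to
# `idx`, by deflated power iteration on D^-1/2 W D^-1/2 + I (the leading
# eigenvector is known analytically, sqrt(d)).
.fiedler <- function(W, idx) {
  s <- length(idx)
  Wi <- W[idx, idx, drop = FALSE]
  d <- rowSums(Wi)
  d[d <= 0] <- 1e-12
  ds <- 1 / sqrt(d)
  v1 <- sqrt(d); v1 <- v1 / sqrt(sum(v1^2))
  if (s <= 400L) {
    N <- Wi * outer(ds, ds)
    ev <- eigen((N + t(N)) / 2, symmetric = TRUE)
    return(ev$vectors[, 2L] * ds)
  }
  x <- seq_len(s) - (s + 1) / 2
  x <- x - sum(x * v1) * v1
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(1000L)) {
    y <- ds * (Wi %*% (ds * x)) + x          # (N + I) x
    y <- y - sum(y * v1) * v1
    ny <- sqrt(sum(y^2))
    if (ny == 0) break
    y <- as.vector(y) / ny
    delta <- sqrt(sum((y - x * sign(sum(y * x) + 1e-300))^2))
    x <- y
    if (delta < 1e-10) break
  }
  x * ds
}

#' Global-to-local hierarchical spectral segmentation
#'
#' Recursive two-way spectral partition of the template vertices: at each
#' step a segment is split by the sign of the Fiedler vector of the
#' symmetric normalized Laplacian of its similarity submatrix (zero entries
#' join the smaller side). Run to L levels this yields 2^L - 1 segments
#' (127 at the default 7) counting all levels including the whole face,
#' unless a split would create a segment smaller than \code{minSize}, in
#' which case that branch stops (with a warning) and its vertices carry
#' their segment forward through deeper levels.
#'
#' @param similarity symmetric nonnegative matrix from
#'   \code{\link{vertexSimilarity}}.
#' @param levels hierarchy depth L (default 7).
#' @param minSize minimum segment size; set 1 to disable the guard.
#' @return a \linkS4class{SegmentHierarchy}. Segment ids follow heap
#'   numbering: the face is 1, the children of k are 2k and 2k + 1.
#' @export
hierarchicalSegmentation <- function(similarity, levels = 7L, minSize = 10L) {
  p <- nrow(similarity)
  if (p != ncol(similarity)) stop("similarity must be square")
  if (levels < 1L) stop("levels must be >= 1")
  members <- list("1" = seq_len(p))
  tab <- data.frame(id = 1L, level = 1L, parent = NA_integer_, size = p)
  assignment <- matrix(1L, p, levels)
  stopped <- FALSE
  for (lev in seq_len(levels - 1L)) {
    ids <- tab$id[tab$level == lev]
    for (id in ids) {
      mem <- members[[as.character(id)]]
      ok <- FALSE
      if (length(mem) >= 2L * max(minSize, 1L)) {
        fv <- .fiedler(similarity, mem)
        neg <- fv < 0
        nn <- sum(neg); np <- sum(fv > 0)
        zeros <- fv == 0
        if (any(zeros)) {                    # ties join the smaller side
          if (nn <= np) neg[zeros] <- TRUE
          nn <- sum(neg)
        }
        if (nn >= max(minSize, 1L) && (length(mem) - nn) >= max(minSize, 1L))
          ok <- TRUE
      }
      if (ok) {
        left <- mem[neg]; right <- mem[!neg]
        for (side in 1:2) {
          cid <- 2L * id + side - 1L
          cm <- if (side == 1L) left else right
          members[[as.character(cid)]] <- cm
          tab <- rbind(tab, data.frame(id = cid, level = lev + 1L,
                                       parent = id, size = length(cm)))
          assignment[cm, lev + 1L] <- cid
        }
      } else {
        stopped <- TRUE
        assignment[mem, lev + 1L] <- assignment[mem, lev]
      }
    }
  }
  if (stopped)
    warning(sprintf("min-size guard stopped one or more branches: %d of %d segments",
                    nrow(tab), 2L^levels - 1L))
  new("SegmentHierarchy", nLevels = as.integer(levels), table = tab,
      members = members, assignment = assignment)
}

#' Per-segment shape principal components with parallel-analysis retention
#'
#' PCA of the individuals x (3 * segment vertices) displacement block of one
#' segment. The number of retained components is chosen by parallel
#' analysis: components whose covariance eigenvalue exceeds the 95th
#' percentile of the corresponding rank's eigenvalue over \code{nNull}
#' column-permuted null datasets (retention stops at the first failure).
#' Score signs are fixed by making each component's largest-magnitude
#' loading positive.
#'
#' @param fields displacement array (vertices x 3 x individuals).
#' @param segment integer vector of segment vertex ids.
#' @param nNull number of null permutations (>= 20; default 100).
#' @param seed RNG seed for the permutation null.
#' @param quantile null quantile (default 0.95).
#' @return list(nRetained, scores, loadings, explained, eigenvalues,
#'   nullQuantiles).
#' @export
segmentPCA <- function(fields, segment, nNull = 100L, seed = 1L,
                       quantile = 0.95) {
  if (nNull < 20L) stop("nNull must be >= 20 (null too coarse)")
  if (length(segment) < 3L) stop("segment must have >= 3 vertices")
  n <- dim(fields)[3L]
  if (n < 10L) stop("need >= 10 individuals")
  X <- matrix(aperm(fields[segment, , , drop = FALSE], c(3L, 2L, 1L)),
              nrow = n)
  X <- scale(X, scale = FALSE)
  m <- ncol(X)
  ev_of <- function(M) {
    # eigenvalues of the covariance via the smaller Gram dimension
    if (m <= n) eigen(crossprod(M) / (n - 1), symmetric = TRUE,
                      only.values = TRUE)$values
    else eigen(tcrossprod(M) / (n - 1), symmetric = TRUE,
               only.values = TRUE)$values
  }
  lambda <- pmax(ev_of(X), 0)
  r <- min(n - 1L, m)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  nullev <- matrix(NA_real_, nNull, r)
  for (b in seq_len(nNull)) {
    # column permutation preserves each column's values (and zero mean)
    P <- .col_permute_cpp(X)
    nullev[b, ] <- pmax(ev_of(P), 0)[seq_len(r)]
  }
  thr <- apply(nullev, 2L, stats::quantile, probs = quantile)
  keep <- 0L
  for (k in seq_len(r)) {
    if (lambda[k] > thr[k]) keep <- k else break
  }
  expl <- lambda[seq_len(r)] / sum(lambda)
  scores <- loadings <- NULL
  if (keep > 0L) {
    sv <- svd(X, nu = keep, nv = keep)
    loadings <- sv$v
    scores <- sv$u %*% diag(sv$d[seq_len(keep)], keep)
    for (k in seq_len(keep)) {
      j <- which.max(abs(loadings[, k]))
      if (loadings[j, k] < 0) {
        loadings[, k] <- -loadings[, k]
        scores[, k] <- -scores[, k]
      }
    }
    rownames(scores) <- dimnames(fields)[[3L]]
  }
  list(nRetained = keep, scores = scores, loadings = loadings,
       explained = expl, eigenvalues = lambda[seq_len(r)],
       nullQuantiles = thr)
}

#' Per-segment surface areas
#'
#' Sum of the areas of the faces assigned to each segment. At each level a
#' face is assigned to the segment holding the majority of its vertices
#' (all three in different segments: the first vertex decides), so the
#' per-level areas conserve the whole-mesh area exactly.
#'
#' @param mesh a \linkS4class{SurfaceMesh} in template correspondence.
#' @param hierarchy a \linkS4class{SegmentHierarchy}.
#' @return named numeric vector of areas (mm^2) per segment id.
#' @export
segmentSurfaceAreas <- function(mesh, hierarchy) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 2L], ] - v[f[, 1L], ]
  b <- v[f[, 3L], ] - v[f[, 1L], ]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  farea <- sqrt(cx^2 + cy^2 + cz^2) / 2
  out <- numeric(nrow(hierarchy@table))
  names(out) <- as.character(hierarchy@table$id)
  for (lev in seq_len(hierarchy@nLevels)) {
    s1 <- hierarchy@assignment[f[, 1L], lev]
    s2 <- hierarchy@assignment[f[, 2L], lev]
    s3 <- hierarchy@assignment[f[, 3L], lev]
    seg <- ifelse(s2 == s3, s2, s1)  # majority; 3-way tie: first vertex
    lv_ids <- unique(hierarchy@assignment[, lev])
    sums <- rowsum(farea, seg)
    hit <- intersect(rownames(sums), names(out)[hierarchy@table$level == lev])
    out[hit] <- sums[hit, 1L]
  }
  out
}

#' k-nearest-neighbour spatial weights on the facial plane
#'
#' Proximity weights for Moran's I over a segment's vertices: k nearest
#' neighbours on the (x, y) vertex locations, symmetrised (union) and then
#' row-standardised.
#'
#' @param xy numeric matrix (n x 2) of vertex locations.
#' @param k neighbours per vertex (default 8).
#' @param rowStandardize divide each row by its sum (default TRUE).
#' @return sparse \code{dgCMatrix} of weights with zero diagonal.
#' @export
spatialWeights <- function(xy, k = 8L, rowStandardize = TRUE) {
  n <- nrow(xy)
  if (n < 2L) stop("need >= 2 locations")
  k <- min(k, n - 1L)
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  idx <- apply(D, 1L, function(r) order(r)[seq_len(k)])
  i <- rep(seq_len(n), each = k)
  j <- as.vector(idx)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  W <- 1 * ((W + Matrix::t(W)) > 0)  # symmetric before standardisation
  if (rowStandardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  methods::as(W, "CsparseMatrix")
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I of an attribute over locations with proximity weights:
#' I = n / sum(w) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2.
#' Its expected value under random permutation of the attribute is
#' -1/(n - 1). Attributes used on facial segments are the z coordinate,
#' mean curvature and Gaussian curvature, over (x, y) vertex locations.
#'
#' @param attribute numeric vector (length n, non-constant).
#' @param weights n x n weight matrix (e.g. \code{\link{spatialWeights}}).
#' @return Moran's I (numeric scalar).
#' @export
moranI <- function(attribute, weights) {
  n <- length(attribute)
  if (n < 5L) stop("need >= 5 locations")
  z <- attribute - mean(attribute)
  den <- sum(z^2)
  if (den == 0) stop("constant attribute: Moran's I undefined")
  s0 <- sum(weights)
  num <- sum(z * as.vector(weights %*% z))
  (n / s0) * (num / den)
}
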