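#' @include AllClasses.R dictionary.R
NULL

#' Average two landmarking replicates
#'
#' Coordinate-wise midpoint of the two replicates of one individual; the
#' averaged coordinates are what all downstream phenotyping uses.
#'
#' @param rep1,rep2 \linkS4class{LandmarkSet}s of the same individual with
#'   identical landmark batteries.
#' @return a \linkS4class{LandmarkSet} (replicate id "mean").
#' @export
averageReplicates <- function(rep1, rep2) {
  stopifnot(is(rep1, "LandmarkSet"), is(rep2, "LandmarkSet"))
  if (!identical(rep1@individual, rep2@individual))
    stop("replicates belong to different individuals: ",
         rep1@individual, " vs ", rep2@individual)
  if (!identical(rownames(rep1@coords), rownames(rep2@coords)))
    stop("replicates use different landmark batteries")
  LandmarkSet((rep1@coords + rep2@coords) / 2,
              individual = rep1@individual, replicate = "mean")
}

#' Landmarking reproducibility table
#'
#' For every landmark and axis, the SD across individuals of the signed
#' between-replicate difference (rep1 - rep2), computed in the raw scanner
#' frame (landmarking happens before alignment). With isotropic per-landmark
#' noise of SD sigma on each replicate, these SDs estimate sigma*sqrt(2).
#' Coordinates with SD <= 1 mm are classed \code{"moderate_or_high"}, the
#' rest \code{"low"}.
#'
#' @param population a \linkS4class{FacePopulation} with two replicates.
#' @param threshold class boundary in mm (default 1).
#' @return data.frame with 3 rows per landmark: landmark, axis, sd, class.
#' @export
reproducibility <- function(population, threshold = 1) {
  stopifnot(is(population, "FacePopulation"))
  n <- length(population@landmarksA)
  if (n < 2L) stop("reproducibility SD undefined for fewer than 2 individuals")
  diffs <- vapply(seq_len(n), function(i)
    population@landmarksA[[i]]@coords - population@landmarksB[[i]]@coords,
    matrix(0, nrow(population@landmarksA[[1L]]@coords), 3L))
  lmn <- rownames(population@landmarksA[[1L]]@coords)
  sds <- apply(diffs, c(1L, 2L), stats::sd)
  out <- data.frame(
    landmark = rep(lmn, 3L),
    axis = rep(c("x", "y", "z"), each = length(lmn)),
    sd = as.vector(sds))
  out$class <- ifelse(out$sd <= threshold, "moderate_or_high", "low")
  out
}

#' Intraclass correlation, two-way mixed model, consistency
#'
#' ICC(3,1) (single measures) and ICC(3,k) (average measures) from the
#' two-way mean squares: ICC(3,1) = (MS_subjects - MS_error) /
#' (MS_subjects + (k-1) MS_error), with 95 percent confidence bounds from
#' the exact F distribution of MS_subjects/MS_error. Consistency ICC is
#' insensitive to constant rater offsets. Qualitative bands follow the
#' common 0.5 / 0.75 / 0.9 convention (poor / moderate / good / excellent).
#'
#' @param ratings numeric matrix, subjects x raters.
#' @param conf confidence level (default 0.95).
#' @return list with components \code{single} and \code{average}, each a
#'   list(icc, lower, upper, label), plus \code{n}, \code{k}.
#' @export
iccConsistency <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 raters")
  if (stats::var(as.vector(ratings)) == 0)
    stop("constant ratings: ICC undefined")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  ss_tot <- sum((ratings - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (mse <= 0 && msr <= 0) stop("degenerate ratings: ICC undefined")
  icc1 <- (msr - mse) / (msr + (k - 1) * mse)
  icck <- (msr - mse) / msr
  fobs <- msr / mse
  a <- 1 - conf
  fl <- fobs / stats::qf(1 - a / 2, n - 1, (n - 1) * (k - 1))
  fu <- fobs * stats::qf(1 - a / 2, (n - 1) * (k - 1), n - 1)
  band <- function(x) {
    if (x < 0.5) "poor" else if (x < 0.75) "moderate"
    else if (x < 0.9) "good" else "excellent"
  }
  list(
    single = list(icc = icc1,
                  lower = (fl - 1) / (fl + k - 1),
                  upper = (fu - 1) / (fu + k - 1),
                  label = band(icc1)),
    average = list(icc = icck, lower = 1 - 1 / fl, upper = 1 - 1 / fu,
                   label = band(icck)),
    n = n, k = k)
}

# Optimal rotation (det +1) aligning centred configuration X onto Y (Kabsch).
.kabsch <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis without scaling
#'
#' Iteratively superimposes landmark configurations by removing translation
#' (centring) and rotation (orthogonal Procrustes with det(R) = +1, so no
#' reflection), deliberately leaving scale untouched to preserve face-size
#' differences. The consensus is initialised from the first configuration
#' and iterated until its RMS change falls below \code{tol}.
#'
#' @param sets list of \linkS4class{LandmarkSet}s (>= 2), same battery.
#' @param scale retained for interface compatibility; only FALSE (the
#'   default and the study design) is supported.
#' @param tol consensus RMS change tolerance in mm (default 1e-8).
#' @param maxIter iteration cap (default 100).
#' @return a \linkS4class{ProcrustesAlignment}.
#' @export
gpa <- function(sets, scale = FALSE, tol = 1e-8, maxIter = 100L) {
  if (length(sets) < 2L) stop("GPA needs at least 2 configurations")
  if (isTRUE(scale)) stop("scaling is deliberately unsupported (sizes preserved)")
  lmn <- rownames(sets[[1L]]@coords)
  p <- length(lmn)
  X <- vapply(sets, function(s) {
    if (!identical(rownames(s@coords), lmn))
      stop("all sets must share one landmark battery")
    s@coords
  }, matrix(0, p, 3L))
  n <- dim(X)[3L]
  cent <- t(apply(X, 3L, colMeans))
  for (i in seq_len(n)) X[, , i] <- sweep(X[, , i], 2L, cent[i, ])
  for (i in seq_len(n)) {
    if (qr(X[, , i])$rank < 2L)
      stop("degenerate configuration ", i, ": all landmarks collinear")
  }
  rot <- rep(list(diag(3)), n)
  cons <- X[, , 1L]
  obj <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- .kabsch(X[, , i], cons)
      X[, , i] <- X[, , i] %*% R
      rot[[i]] <- rot[[i]] %*% R
    }
    new_cons <- apply(X, c(1L, 2L), mean)
    obj <- c(obj, sum(sweep(X, c(1L, 2L), new_cons)^2))
    delta <- sqrt(mean((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
    if (iter >= maxIter)
      stop(sprintf("GPA did not converge in %d iterations (last RMS change %.3g)",
                   maxIter, delta))
  }
  dimnames(X) <- list(lmn, c("x", "y", "z"),
                      vapply(sets, function(s) s@individual, ""))
  rownames(cons) <- lmn; colnames(cons) <- c("x", "y", "z")
  new("ProcrustesAlignment", aligned = X, consensus = cons, rotations = rot,
      translations = cent, objective = obj, iterations = iter)
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid. Unchanged by \code{\link{gpa}}, which removes only translation
#' and rotation.
#'
#' @param x a \linkS4class{LandmarkSet} or coordinate matrix.
#' @return numeric scalar (mm).
#' @export
centroidSize <- function(x) {
  m <- if (is(x, "LandmarkSet")) x@coords else as.matrix(x)
  sqrt(sum(scale(m, scale = FALSE)^2))
}
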