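#' @include AllClasses.R io.R
NULL

#' Bonferroni per-test significance threshold
#'
#' \code{alpha / nTests}; with alpha = 0.05 over 14,838 phenotypes the
#' threshold is 3.37e-6.
#'
#' @param alpha family-wise error rate (in (0, 1)).
#' @param nTests number of tests (>= 1).
#' @return per-test threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}

# Spearman rho of every column of X against y, with average-rank ties and
# two-sided p from the t approximation. Vectorised across columns.
.spearman_screen <- function(X, y) {
  n <- length(y)
  ry <- rank(y)
  RX <- apply(X, 2L, rank)
  rho <- suppressWarnings(stats::cor(RX, ry))[, 1L]
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Screen phenotypes for regional differences
#'
#' Correlates each phenotype with the ordinal region coding (north = 1 <
#' central = 2 < south = 3) by Spearman rho (average-rank ties, two-sided
#' t-approximation p), applies the Bonferroni threshold alpha / P over the P
#' phenotypes tested, and labels significant phenotypes heterogeneous and
#' the rest homogeneous. A Kruskal-Wallis screen (no ordinal assumption) is
#' available via \code{method = "kruskal"}.
#'
#' @param x a \linkS4class{FacePhenotypes} or individuals-x-phenotypes matrix.
#' @param regions per-individual region labels; a factor whose level order
#'   encodes the geographic order, or a character vector matched against
#'   \code{regionOrder}.
#' @param alpha family-wise error rate (default 0.05).
#' @param regionOrder explicit north-to-south level order (default: factor
#'   levels, or sorted unique values).
#' @param method "spearman" (default) or "kruskal".
#' @return data.frame per phenotype: phenotype, rho (NA for kruskal), p,
#'   significant, label ("heterogeneous"/"homogeneous"; NA for constant
#'   phenotypes, with a warning).
#' @export
regionScreen <- function(x, regions, alpha = 0.05, regionOrder = NULL,
                         method = c("spearman", "kruskal")) {
  method <- match.arg(method)
  X <- if (is(x, "FacePhenotypes")) phenotypeValues(x) else as.matrix(x)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("phenotype", seq_len(ncol(X)))
  if (is.null(regionOrder))
    regionOrder <- if (is.factor(regions)) levels(regions)
                   else sort(unique(regions))
  if (length(regionOrder) < 2L) stop("need >= 2 region levels")
  y <- match(as.character(regions), regionOrder)
  if (anyNA(y)) stop("region label outside regionOrder")
  const <- apply(X, 2L, function(v) stats::var(v, na.rm = TRUE)) == 0
  const[is.na(const)] <- TRUE
  if (any(const))
    warning(sum(const), " constant phenotype(s) screened as NA")
  thr <- bonferroniThreshold(alpha, ncol(X))
  rho <- p <- rep(NA_real_, ncol(X))
  work <- which(!const)
  if (length(work)) {
    if (method == "spearman") {
      sc <- .spearman_screen(X[, work, drop = FALSE], y)
      rho[work] <- sc$rho; p[work] <- sc$p
    } else {
      p[work] <- apply(X[, work, drop = FALSE], 2L, function(v)
        stats::kruskal.test(v, factor(y))$p.value)
    }
  }
  sig <- !is.na(p) & p < thr
  data.frame(phenotype = colnames(X), rho = rho, p = p, significant = sig,
             label = ifelse(is.na(p), NA_character_,
                            ifelse(sig, "heterogeneous", "homogeneous")),
             row.names = NULL)
}

#' Chi-square test of design balance
#'
#' Pearson chi-square (no continuity correction) on a contingency table,
#' e.g. region x sex counts, with df = (r-1)(c-1).
#'
#' @param table matrix of counts.
#' @return list(statistic, df, p, expected).
#' @export
chi2Balance <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- stats::chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("non-positive expected count")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

# one NIPALS PLS2 fit of (pre-scaled) X on one-hot (centred) Y
.nipals_pls <- function(X, Y, ncomp, tol = 1e-10, maxit = 500L) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  Q <- matrix(0, q, ncomp)
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  R2X <- R2Y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(0, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u); w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      qv <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pv <- crossprod(X, tt) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pv; Q[, a] <- qv
    X <- X - tcrossprod(tt, pv)
    Y <- Y - tcrossprod(tt, qv)
    R2X[a] <- 1 - sum(X^2) / ssx0
    R2Y[a] <- 1 - sum(Y^2) / ssy0
  }
  list(W = W, P = P, T = Tm, Q = Q, R2X = R2X, R2Y = R2Y)
}

.vip <- function(fit, ncomp) {
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  p <- nrow(W)
  ssy <- diff(c(0, fit$R2Y[seq_len(ncomp)]))  # Y variance per component
  Wn2 <- sweep(W, 2L, sqrt(colSums(W^2)), "/")^2
  v <- sqrt(p * as.vector(Wn2 %*% ssy) / sum(ssy))
  v
}

#' PLS-DA with VIP variable selection
#'
#' NIPALS PLS2 regression of one-hot group membership on autoscaled
#' phenotypes (mean 0, unit variance). The component count is chosen by
#' cross-validated Q2: components are added while the Q2 gain is at least
#' \code{q2Gain} (capped at \code{maxComp}). Per-variable VIP scores
#' summarise discriminatory power across components
#' (VIP_j = sqrt(p * sum_a ssy_a (w_ja/||w_a||)^2 / sum_a ssy_a)); they
#' satisfy sum(VIP^2) = p, and VIP > 1 is the conventional selection rule.
#'
#' @param x individuals-x-phenotypes matrix or \linkS4class{FacePhenotypes}.
#' @param groups group labels (>= 2 levels, >= 2 samples each).
#' @param maxComp maximum components (default 10).
#' @param cvFolds cross-validation folds for Q2 (default 7).
#' @param seed seed for the fold split.
#' @param q2Gain minimum Q2 improvement to add a component (default 0.01).
#' @return a \linkS4class{PlsdaModel}.
#' @export
plsda <- function(x, groups, maxComp = 10L, cvFolds = 7L, seed = 1L,
                  q2Gain = 0.01) {
  X0 <- if (is(x, "FacePhenotypes")) phenotypeValues(x) else as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group")
  n <- nrow(X0)
  keep <- which(apply(X0, 2L, stats::sd) > 0)
  X0 <- X0[, keep, drop = FALSE]
  ctr <- colMeans(X0); scl <- apply(X0, 2L, stats::sd)
  Xs <- scale(X0, center = ctr, scale = scl)
  Y0 <- stats::model.matrix(~ groups - 1)
  colnames(Y0) <- levels(groups)
  Ys <- scale(Y0, scale = FALSE)
  maxComp <- min(maxComp, ncol(Xs), n - 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  folds <- sample(rep(seq_len(cvFolds), length.out = n))
  press <- matrix(0, maxComp, 1L)
  for (f in seq_len(cvFolds)) {
    tr <- folds != f; te <- !tr
    ctr_f <- colMeans(X0[tr, , drop = FALSE])
    scl_f <- apply(X0[tr, , drop = FALSE], 2L, stats::sd)
    scl_f[scl_f == 0] <- 1
    Xtr <- scale(X0[tr, , drop = FALSE], ctr_f, scl_f)
    yctr <- colMeans(Y0[tr, , drop = FALSE])
    Ytr <- scale(Y0[tr, , drop = FALSE], yctr, FALSE)
    fit <- .nipals_pls(Xtr, Ytr, maxComp)
    Xte <- scale(X0[te, , drop = FALSE], ctr_f, scl_f)
    Yte <- scale(Y0[te, , drop = FALSE], yctr, FALSE)
    # accumulate predictions component by component
    pred <- matrix(0, sum(te), ncol(Y0))
    Xres <- Xte
    for (a in seq_len(maxComp)) {
      tte <- Xres %*% fit$W[, a]
      pred <- pred + tcrossprod(tte, fit$Q[, a])
      Xres <- Xres - tcrossprod(tte, fit$P[, a])
      press[a] <- press[a] + sum((Yte - pred)^2)
    }
  }
  ssy_tot <- sum(Ys^2)
  q2cum <- 1 - press[, 1L] / ssy_tot
  ncomp <- 1L
  while (ncomp < maxComp && (q2cum[ncomp + 1L] - q2cum[ncomp]) >= q2Gain)
    ncomp <- ncomp + 1L
  fit <- .nipals_pls(Xs, Ys, ncomp)
  vipv <- .vip(fit, ncomp)
  names(vipv) <- colnames(X0)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X0)
  rownames(fit$T) <- rownames(X0)
  new("PlsdaModel", ncomp = as.integer(ncomp), weights = fit$W,
      loadings = fit$P, scores = fit$T, yloadings = fit$Q, vip = vipv,
      R2X = fit$R2X, R2Y = fit$R2Y, Q2 = q2cum[seq_len(ncomp)],
      center = ctr, scale = scl, groups = levels(groups))
}

#' PERMANOVA (Adonis): permutation test on a distance matrix
#'
#' Partitions the total sum of squared distances by group labels (Gower
#' centring of -d^2/2), reports the pseudo-F and R^2 = SS_between/SS_total,
#' and tests F by permuting labels: p = (1 + #{F_perm >= F_obs}) /
#' (1 + nPerm). Default distance: Euclidean on standardised phenotypes.
#'
#' @param x individuals-x-variables matrix, \linkS4class{FacePhenotypes}, or
#'   a \code{dist} object.
#' @param groups group labels (>= 2 levels).
#' @param nPerm permutations (>= 99; default 999).
#' @param seed RNG seed for the permutations.
#' @param standardize autoscale columns before the Euclidean distance
#'   (ignored for \code{dist} input; default TRUE).
#' @return list(F, R2, p, nPerm, seed, df).
#' @export
permanova <- function(x, groups, nPerm = 999L, seed = 1L,
                      standardize = TRUE) {
  if (nPerm < 99L) stop("nPerm must be >= 99")
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("need >= 2 groups")
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    X <- if (is(x, "FacePhenotypes")) phenotypeValues(x) else as.matrix(x)
    if (standardize) {
      s <- apply(X, 2L, stats::sd)
      X <- scale(X[, s > 0, drop = FALSE])
    }
    D <- as.matrix(stats::dist(X))
  }
  n <- nrow(D)
  if (length(groups) != n) stop("groups length does not match distances")
  A <- -D^2 / 2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  sst <- sum(diag(G))
  fstat <- function(idx) {
    gs <- groups[idx]
    # SS_between = sum over groups of ||group mean||^2 contributions:
    # tr(H G H) with H the hat matrix of the one-hot design
    ssb <- 0
    for (lv in levels(gs)) {
      m <- gs == lv
      ssb <- ssb + sum(G[m, m]) / sum(m)
    }
    ssw <- sst - ssb
    c(F = (ssb / (g - 1)) / (ssw / (n - g)), R2 = ssb / sst)
  }
  obs <- fstat(seq_len(n))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    if (fstat(sample.int(n))[1L] >= obs[1L]) exceed <- exceed + 1L
  }
  list(F = unname(obs[1L]), R2 = unname(obs[2L]),
       p = (1 + exceed) / (1 + nPerm), nPerm = nPerm, seed = seed,
       df = c(between = g - 1L, within = n - g))
}

#' Remove the linear age effect from every phenotype
#'
#' Replaces each phenotype by the residuals of its least-squares regression
#' on age, with the phenotype mean added back. Idempotent; phenotypes
#' uncorrelated with age are unchanged up to numerical tolerance.
#'
#' @param x \linkS4class{FacePhenotypes} or individuals-x-phenotypes matrix.
#' @param age numeric vector of ages (finite, non-constant). Defaults to
#'   \code{colData(x)$age} for a \linkS4class{FacePhenotypes}.
#' @return same class as the input, with adjusted values.
#' @export
ageAdjust <- function(x, age = NULL) {
  isFP <- is(x, "FacePhenotypes")
  X <- if (isFP) phenotypeValues(x) else as.matrix(x)
  if (is.null(age)) {
    if (!isFP) stop("age must be given for matrix input")
    age <- SummarizedExperiment::colData(x)$age
  }
  age <- as.numeric(age)
  if (!all(is.finite(age))) stop("age must be finite")
  if (stats::var(age) == 0) stop("constant age: adjustment undefined")
  ac <- age - mean(age)
  beta <- crossprod(X, ac) / sum(ac^2)
  adj <- X - outer(ac, as.vector(beta))
  if (!isFP) return(adj)
  rd <- SummarizedExperiment::rowData(x)
  FacePhenotypes(adj, category = rd$category, units = rd$units,
                 sampleData = as.data.frame(SummarizedExperiment::colData(x)))
}
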