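make_small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulatePopulation(small_template(), populationModel(),
                                   nPerRegion = 10, seed = 19)
    cache
  }
})

test_that("displacement fields vanish for the template and track landmarks", {
  tpl <- small_template()
  model0 <- populationModel(gradientTraits = defaultGradientTraits()[0, ],
                            sigmaInd = 0, sigmaMeas = 0,
                            sexEffect = matrix(0, 26, 3),
                            ageEffect = matrix(0, 26, 3))
  pop0 <- simulatePopulation(tpl, model0, nPerRegion = 1, seed = 1)
  f0 <- displacementField(pop0)
  expect_lt(max(abs(f0)), 1e-8)
  # landmark-vertex displacement magnitudes track the simulated landmarks
  pop <- make_small_pop()
  fields <- displacementField(pop)
  avg <- mapply(averageReplicates, pop@landmarksA, pop@landmarksB,
                SIMPLIFY = FALSE)
  al <- gpa(avg)
  tlm <- coords(templateLandmarks(tpl))
  Rt <- faceMorph:::.kabsch(scale(tlm, scale = FALSE), al@consensus)
  tal <- scale(tlm, scale = FALSE) %*% Rt
  for (i in c(1, 12)) {
    lm_disp <- al@aligned[, , i] - tal
    fld <- fields[tpl@landmarkIndex, , i]
    # mesh was warped to true landmarks; replicate-average adds noise ~0.35mm
    expect_lt(sqrt(mean((fld - lm_disp)^2)), 0.8)
  }
})

test_that("vertex similarity is an RV coefficient in [0, 1]", {
  set.seed(41)
  n <- 60
  latent <- rnorm(n)
  f <- array(rnorm(4 * 3 * n, sd = 0.05), c(4, 3, n))
  f[1, 1, ] <- f[1, 1, ] + latent
  f[2, 1, ] <- f[2, 1, ] + latent       # vertex 2 driven by the same factor
  S <- vertexSimilarity(f)
  expect_true(all(S >= -1e-12 & S <= 1 + 1e-12))
  expect_equal(diag(S), rep(1, 4))
  expect_equal(S, t(S))
  expect_gt(S[1, 2], 0.9)
  # independent-noise similarity stays low at large n
  set.seed(42)
  f2 <- array(rnorm(2 * 3 * 500), c(2, 3, 500))
  S2 <- vertexSimilarity(f2)
  expect_lt(S2[1, 2], 0.15)
  # perfect covariation without noise
  f3 <- array(0, c(2, 3, 50))
  f3[1, 1, ] <- rnorm(50); f3[2, 2, ] <- 2 * f3[1, 1, ]
  expect_equal(vertexSimilarity(f3)[1, 2], 1, tolerance = 1e-12)
})

test_that("planted two-block similarity is recovered exactly at level 2", {
  set.seed(43)
  n <- 80
  truth <- rep(1:2, each = n / 2)
  S <- matrix(0.1, n, n)
  S[truth == 1, truth == 1] <- 0.9
  S[truth == 2, truth == 2] <- 0.9
  diag(S) <- 1
  h <- hierarchicalSegmentation(S, levels = 2, minSize = 5)
  expect_equal(nrow(segmentTable(h)), 3L)
  got <- h@assignment[, 2]
  expect_true(all(table(got, truth) %in% c(0L, n / 2)))  # Rand index 1
  h1 <- hierarchicalSegmentation(S, levels = 1)
  expect_equal(segmentMembers(h1, 1), seq_len(n))
})

test_that("hierarchy is a consistent recursive partition with 2^L - 1 segments", {
  pop <- make_small_pop()
  fields <- displacementField(pop)
  S <- vertexSimilarity(fields)
  h <- hierarchicalSegmentation(S, levels = 5, minSize = 10)
  tab <- segmentTable(h)
  expect_equal(nrow(tab), 2^5 - 1)
  for (lev in 1:5) {
    segs <- tab$id[tab$level == lev]
    mem <- unlist(lapply(segs, segmentMembers, x = h))
    expect_equal(sort(mem), seq_len(nrow(S)))    # disjoint cover per level
  }
  for (r in which(tab$level > 1)) {
    expect_true(all(segmentMembers(h, tab$id[r]) %in%
                      segmentMembers(h, tab$parent[r])))
  }
  kids <- tab[tab$level == 3, ]
  for (par in unique(kids$parent)) {
    expect_equal(sort(unlist(lapply(kids$id[kids$parent == par],
                                    segmentMembers, x = h))),
                 sort(segmentMembers(h, par)))
  }
})

test_that("parallel analysis retains planted rank and rejects pure noise", {
  set.seed(44)
  n <- 200; nv <- 10
  latent <- rnorm(n, sd = 5)
  load <- rnorm(3 * nv); load <- load / sqrt(sum(load^2))
  f <- array(0, c(nv, 3, n))
  for (i in seq_len(n))
    f[, , i] <- matrix(latent[i] * load, nv, 3) +
      matrix(rnorm(3 * nv, sd = 0.1), nv, 3)
  pc <- segmentPCA(f, seq_len(nv), nNull = 100, seed = 2)
  expect_equal(pc$nRetained, 1L)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # isotropic noise: retains at most 1 component in >= 95% of seeded runs
  kept <- vapply(1:50, function(b) {
    set.seed(100 + b)
    fn <- array(rnorm(nv * 3 * 200), c(nv, 3, 200))
    segmentPCA(fn, seq_len(nv), nNull = 30, seed = b)$nRetained
  }, 0L)
  expect_gte(mean(kept <= 1), 0.95)
  expect_error(segmentPCA(f, seq_len(nv), nNull = 10), "nNull")
  # bit-wise reproducibility given the seed
  a <- segmentPCA(f, seq_len(nv), nNull = 50, seed = 7)
  b <- segmentPCA(f, seq_len(nv), nNull = 50, seed = 7)
  expect_identical(a$scores, b$scores)
  # sign convention: largest-magnitude loading positive
  expect_gt(a$loadings[which.max(abs(a$loadings[, 1])), 1], 0)
})

test_that("segment areas conserve the whole-mesh area level by level", {
  g <- make_grid_mesh(3, 2, 1, 1)  # unit square split into triangles
  idx <- seq_len(6)
  h1 <- hierarchicalSegmentation(matrix(1, 6, 6), levels = 1)
  a1 <- segmentSurfaceAreas(g$mesh, h1)
  expect_equal(unname(a1["1"]), 1)
  pop <- make_small_pop()
  fields <- displacementField(pop)
  S <- vertexSimilarity(fields)
  h <- hierarchicalSegmentation(S, levels = 4, minSize = 10)
  mesh <- pop@meshes[[1]]
  areas <- segmentSurfaceAreas(mesh, h)
  tab <- segmentTable(h)
  total <- areas[as.character(tab$id[tab$level == 1])]
  for (lev in 2:4) {
    lv <- sum(areas[as.character(tab$id[tab$level == lev])])
    expect_equal(unname(lv), unname(total), tolerance = 0.02)
  }
  # icosphere octant: area about 4*pi*r^2/8 (rotated so no vertex sits
  # exactly on an octant boundary plane and the majority rule is unbiased)
  set.seed(99)
  R <- random_rotation()
  sph0 <- make_icosphere(4, 20)
  v <- vertices(sph0) %*% R
  sph <- SurfaceMesh(v, faces(sph0))
  oct <- which(v[, 1] > 0 & v[, 2] > 0 & v[, 3] > 0)
  rest <- setdiff(seq_len(nrow(v)), oct)
  h2 <- new("SegmentHierarchy", nLevels = 2L,
            table = data.frame(id = c(1L, 2L, 3L), level = c(1L, 2L, 2L),
                               parent = c(NA, 1L, 1L),
                               size = c(nrow(v), length(oct), length(rest))),
            members = list("1" = seq_len(nrow(v)), "2" = oct, "3" = rest),
            assignment = cbind(rep(1L, nrow(v)),
                               ifelse(seq_len(nrow(v)) %in% oct, 2L, 3L)))
  a2 <- segmentSurfaceAreas(sph, h2)
  expect_equal(unname(a2["2"]), 4 * pi * 20^2 / 8, tolerance = 0.05)
})

test_that("Moran's I matches its permutation null mean and sign structure", {
  set.seed(45)
  g <- expand.grid(x = 1:12, y = 1:12)
  W <- spatialWeights(as.matrix(g), k = 4)
  n <- nrow(g)
  att <- rnorm(n)
  perm_mean <- mean(replicate(2000, moranI(sample(att), W)))
  expect_equal(perm_mean, -1 / (n - 1), tolerance = 0.15,
               ignore_attr = TRUE)
  # smooth gradient: strong positive autocorrelation
  expect_gt(moranI(g$x + g$y, W), 0.5)
  # checkerboard: negative autocorrelation
  expect_lt(moranI((-1)^(g$x + g$y), W), 0)
  # affine invariance of the attribute
  a1 <- moranI(att, W)
  expect_equal(moranI(3 * att - 7, W), a1, tolerance = 1e-12)
  expect_error(moranI(rep(1, n), W), "constant")
  # cross-check against an independent implementation
  skip_if_not_installed("ape")
  Wd <- as.matrix(W)
  expect_equal(moranI(att, Wd), ape::Moran.I(att, Wd)$observed,
               tolerance = 1e-12)
})

test_that("spatial weights are symmetric before row-standardisation", {
  set.seed(46)
  xy <- cbind(runif(40), runif(40))
  W0 <- spatialWeights(xy, k = 6, rowStandardize = FALSE)
  expect_equal(as.matrix(W0), t(as.matrix(W0)))
  expect_true(all(diag(as.matrix(W0)) == 0))
  W1 <- spatialWeights(xy, k = 6)
  expect_equal(unname(Matrix::rowSums(W1)), rep(1, 40), tolerance = 1e-12)
})
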