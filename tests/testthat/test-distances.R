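lms_from <- function(m) {
  dict <- defaultLandmarkDictionary()
  rownames(m) <- landmarkNames(dict)[seq_len(nrow(m))]
  LandmarkSet(m)
}

test_that("Euclidean distances satisfy the metric axioms and the 325 count", {
  set.seed(2)
  m <- matrix(rnorm(78, sd = 30), 26, 3)
  m[1, ] <- c(0, 0, 0); m[2, ] <- c(3, 4, 0)
  lms <- lms_from(m)
  d <- euclideanDistances(lms)
  expect_length(d, 325L)
  expect_equal(unname(d[1]), 5)  # 3-4-5 triangle
  D <- matrix(0, 26, 26)
  D[upper.tri(D)] <- d[order(seq_along(d))]
  # rebuild full matrix for the triangle inequality over all triples
  Dm <- as.matrix(dist(m))
  tri <- t(combn(26, 3))
  expect_true(all(Dm[tri[, 1:2]] + Dm[tri[, 2:3]] >=
                    Dm[tri[, c(1, 3)]] - 1e-9))
})

test_that("Manhattan distances dominate Euclidean within the sqrt(3) bound", {
  set.seed(3)
  m <- matrix(rnorm(78, sd = 30), 26, 3)
  m[1, ] <- c(0, 0, 0); m[2, ] <- c(1, 2, 3); m[3, ] <- c(5, 0, 0)
  lms <- lms_from(m)
  man <- manhattanDistances(lms)
  euc <- euclideanDistances(lms)
  expect_equal(unname(man[1]), 6)
  expect_equal(unname(man[paste(landmarkNames(defaultLandmarkDictionary())[1],
                                landmarkNames(defaultLandmarkDictionary())[3],
                                sep = "-")]), 5)  # axis-aligned: equality
  expect_true(all(man >= euc - 1e-12))
  expect_true(all(man / euc <= sqrt(3) + 1e-12))
})

test_that("geodesics are exact on flat sheets and great circles on spheres", {
  g <- make_grid_mesh(61, 41, 120, 80)
  v <- vertices(g$mesh)
  src <- g$index[11, 11]; tgt <- g$index[51, 31]
  d <- geodesicField(g$mesh, src)
  true <- sqrt(sum((v[tgt, ] - v[src, ])^2))
  expect_equal(d[tgt], true, tolerance = 0.01)
  # axis-aligned pair is exact
  tgt2 <- g$index[41, 11]
  expect_equal(d[tgt2], sqrt(sum((v[tgt2, ] - v[src, ])^2)),
               tolerance = 1e-9)
  sph <- make_icosphere(4, 50)
  vs <- vertices(sph)
  i1 <- which.max(vs[, 3])
  i2 <- which.min(colSums((t(vs) - c(50, 0, 0))^2))
  ds <- geodesicField(sph, i1)
  arc <- 50 * acos(sum(vs[i1, ] * vs[i2, ]) / 50^2)
  expect_equal(ds[i2], arc, tolerance = 0.02)
})

test_that("geodesics dominate chords and are bounded by edge-graph Dijkstra", {
  skip_if_not_installed("igraph")
  tpl <- small_template()
  pop <- simulatePopulation(tpl, populationModel(), nPerRegion = 1, seed = 17)
  mesh <- pop@meshes[[1]]
  lms <- averageReplicates(pop@landmarksA[[1]], pop@landmarksB[[1]])
  geo <- geodesicDistances(mesh, lms)
  expect_length(geo, 325L)
  # chord comparison at the snapped vertices the solver actually connects
  snap <- faceMorph:::.snap_landmarks(mesh, lms)
  vs <- vertices(mesh)[snap, ]
  rownames(vs) <- names(snap)
  euc <- euclideanDistances(LandmarkSet(vs))
  expect_true(all(geo >= euc - 1e-6))
  # Dijkstra over mesh edges is a path on the surface: an upper bound
  f <- faces(mesh); v <- vertices(mesh)
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  wts <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  gr <- igraph::graph_from_edgelist(e, directed = FALSE)
  Ddij <- igraph::distances(gr, v = snap, to = snap, weights = wts)
  pr <- faceMorph:::.pair_index(rownames(coords(lms)))
  dij <- Ddij[cbind(pr$i, pr$j)]
  expect_true(all(geo <= dij + 1e-6))
  # far-from-surface landmark rejected
  off <- coords(lms); off["pronasale", 3] <- off["pronasale", 3] + 10
  expect_error(geodesicDistances(mesh, LandmarkSet(off)), "pronasale")
})

test_that("curvature estimates match sphere, plane and saddle analytics", {
  sph <- make_icosphere(4, 10)
  i <- which.max(vertices(sph)[, 3])
  cv <- vertexCurvatures(sph, meshNeighborhoods(sph, 3, i), i)
  expect_equal(cv$MC, 1 / 10, tolerance = 0.05)
  expect_equal(cv$GC, 1 / 100, tolerance = 0.05)
  flat <- make_grid_mesh(21, 21, 40, 40)
  j <- flat$index[11, 11]
  cvf <- vertexCurvatures(flat$mesh, meshNeighborhoods(flat$mesh, 8, j), j)
  expect_lt(abs(cvf$MC), 1e-6)
  expect_lt(abs(cvf$GC), 1e-6)
  saddle <- make_grid_mesh(41, 41, 40, 40,
                           zfun = function(x, y) (x - 20) * (y - 20) / 20)
  k <- saddle$index[21, 21]
  cvs <- vertexCurvatures(saddle$mesh, meshNeighborhoods(saddle$mesh, 6, k), k)
  expect_lt(cvs$GC, 0)
  expect_true(abs(cvs$kmax) >= abs(cvs$kmin))
})

test_that("landmark curvatures have the documented sign structure on faces", {
  tpl <- default_template()
  pop <- simulatePopulation(tpl, populationModel(sigmaInd = 0.3),
                            nPerRegion = 1, seed = 23)
  mesh <- pop@meshes[[1]]
  lms <- averageReplicates(pop@landmarksA[[1]], pop@landmarksB[[1]])
  cv <- landmarkCurvatures(mesh, lms)
  expect_equal(nrow(cv), 26L)
  expect_gt(cv$MC[cv$landmark == "pronasale"], 0)  # nose tip is convex
  expect_true(all(abs(cv$kmax) >= abs(cv$kmin) - 1e-12))
  expect_equal(cv$MC, (cv$kmax + cv$kmin) / 2)
  expect_equal(cv$GC, cv$kmax * cv$kmin)
  expect_error(landmarkCurvatures(mesh, lms, radius = 0.5), "neighbours")
})

test_that("rigid motion leaves invariant families unchanged, Manhattan not", {
  set.seed(6)
  m <- matrix(rnorm(78, sd = 25), 26, 3)
  lms <- lms_from(m)
  R <- random_rotation()
  m2 <- m %*% R + matrix(rep(c(7, -2, 4), each = 26), 26, 3)
  lms2 <- lms_from(m2)
  expect_equal(euclideanDistances(lms2), euclideanDistances(lms),
               tolerance = 1e-9)
  expect_equal(angleMeasurements(lms2), angleMeasurements(lms),
               tolerance = 1e-6)
  expect_equal(triangleAreas(lms2), triangleAreas(lms), tolerance = 1e-6)
  expect_equal(regionVolumeSurface(lms2)$volume,
               regionVolumeSurface(lms)$volume, tolerance = 1e-6)
  expect_gt(max(abs(manhattanDistances(lms2) - manhattanDistances(lms))),
            1)
})
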