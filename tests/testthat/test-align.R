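test_that("replicate averaging is the symmetric coordinate-wise midpoint", {
  dict <- defaultLandmarkDictionary()
  set.seed(1)
  m <- matrix(rnorm(78), 26, 3, dimnames = list(landmarkNames(dict), NULL))
  r1 <- LandmarkSet(m, individual = "a", replicate = "1")
  expect_equal(coords(averageReplicates(r1, r1)), coords(r1),
               ignore_attr = TRUE)
  m2 <- m
  m2["nasion", 1] <- m2["nasion", 1] + 2
  r2 <- LandmarkSet(m2, individual = "a", replicate = "2")
  avg <- averageReplicates(r1, r2)
  expect_equal(unname(coords(avg)["nasion", 1]), unname(m["nasion", 1]) + 1)
  expect_equal(coords(averageReplicates(r2, r1)), coords(avg))
  r3 <- LandmarkSet(m, individual = "b")
  expect_error(averageReplicates(r1, r3), "different individuals")
})

test_that("reproducibility SDs recover the sigma*sqrt(2) law", {
  tpl <- small_template()
  model <- populationModel(sigmaInd = 1, sigmaMeas = 0.5)
  pop <- simulatePopulation(tpl, model, nPerRegion = 170, seed = 21,
                            warpMeshes = FALSE)
  tab <- reproducibility(pop)
  expect_equal(nrow(tab), 78L)
  expect_true(all(tab$sd >= 0))
  # SD of the difference of two independent N(0, 0.5^2) draws = 0.5*sqrt(2)
  expect_lt(max(abs(tab$sd - 0.5 * sqrt(2))), 0.1 * 0.5 * sqrt(2) * 2)
  expect_equal(mean(tab$sd), 0.5 * sqrt(2), tolerance = 0.05)
  # zero noise: all SDs zero
  pop0 <- simulatePopulation(tpl, populationModel(sigmaMeas = 0),
                             nPerRegion = 3, seed = 2, warpMeshes = FALSE)
  expect_true(all(reproducibility(pop0)$sd == 0))
  pop1 <- new("FacePopulation", template = tpl, meshes = list(),
              landmarksA = pop0@landmarksA[1], landmarksB = pop0@landmarksB[1],
              trueLandmarks = pop0@trueLandmarks[1],
              sampleData = pop0@sampleData[1, ])
  expect_error(reproducibility(pop1), "fewer than 2")
})

test_that("a noisy landmark is the only one classed as low reproducibility", {
  tpl <- small_template()
  sm <- rep(0.2, 26)
  names(sm) <- landmarkNames(defaultLandmarkDictionary())
  sm["zygion_L"] <- 3
  pop <- simulatePopulation(tpl, populationModel(sigmaMeas = sm),
                            nPerRegion = 334, seed = 8, warpMeshes = FALSE)
  tab <- reproducibility(pop)
  low <- tab[tab$class == "low", ]
  expect_setequal(unique(low$landmark), "zygion_L")
  expect_equal(nrow(low), 3L)
})

test_that("ICC consistency matches its variance-component closed form", {
  set.seed(31)
  subj <- rnorm(2000, sd = 2)
  ratings <- cbind(subj + rnorm(2000), subj + rnorm(2000))
  ic <- iccConsistency(ratings)
  expect_equal(ic$single$icc, 0.8, tolerance = 0.03 / 0.8)
  expect_lt(ic$single$lower, ic$single$icc)
  expect_gt(ic$single$upper, ic$single$icc)
  # identical raters: ICC 1; constant offset between raters: still 1
  r1 <- rnorm(50)
  expect_equal(iccConsistency(cbind(r1, r1))$single$icc, 1)
  expect_equal(iccConsistency(cbind(r1, r1 + 3))$single$icc, 1)
  expect_error(iccConsistency(matrix(1, 10, 2)), "constant")
})

test_that("GPA removes exactly a rigid transform and matches the Kabsch oracle", {
  dict <- defaultLandmarkDictionary()
  set.seed(5)
  X <- matrix(rnorm(78, sd = 20), 26, 3,
              dimnames = list(landmarkNames(dict), NULL))
  R <- random_rotation()
  Y <- X %*% R + matrix(rep(c(5, -3, 11), each = 26), 26, 3)
  al <- gpa(list(LandmarkSet(X, individual = "a"),
                 LandmarkSet(Y, individual = "b")))
  expect_lt(sqrt(mean((al@aligned[, , 1] - al@aligned[, , 2])^2)), 1e-8)
  expect_error(gpa(list(LandmarkSet(X))), "at least 2")
  # pairwise Procrustes distance after GPA equals the SVD oracle
  for (rep in 1:10) {
    A <- matrix(rnorm(78, sd = 10), 26, 3,
                dimnames = list(landmarkNames(dict), NULL))
    B <- A + matrix(rnorm(78), 26, 3)
    al2 <- gpa(list(LandmarkSet(A, individual = "a"),
                    LandmarkSet(B, individual = "b")))
    d_gpa <- sqrt(sum((al2@aligned[, , 1] - al2@aligned[, , 2])^2))
    # oracle: optimal rigid superposition of B onto A by Kabsch/SVD
    Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
    sv <- svd(crossprod(Bc, Ac))
    Ro <- sv$u %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$v)
    d_oracle <- sqrt(sum((Bc %*% Ro - Ac)^2))
    expect_equal(d_gpa, d_oracle, tolerance = 1e-6)
  }
})

test_that("GPA objective is monotone, reflection-free and size-preserving", {
  tpl <- small_template()
  pop <- simulatePopulation(tpl, populationModel(), nPerRegion = 15, seed = 13,
                            warpMeshes = FALSE)
  sets <- mapply(averageReplicates, pop@landmarksA, pop@landmarksB,
                 SIMPLIFY = FALSE)
  al <- gpa(sets)
  expect_true(all(diff(al@objective) <= 1e-8))
  expect_true(all(vapply(al@rotations, det, 0) > 1 - 1e-8))
  for (i in seq_along(sets))
    expect_equal(centroidSize(al@aligned[, , i]), centroidSize(sets[[i]]),
                 tolerance = 1e-10)
  # result invariant to a rigid pre-transform of one input set
  sets2 <- sets
  set.seed(77)
  R <- random_rotation()
  sets2[[3]] <- LandmarkSet(coords(sets[[3]]) %*% R +
                              matrix(rep(c(10, 20, -5), each = 26), 26, 3),
                            individual = sets[[3]]@individual)
  al2 <- gpa(sets2)
  expect_equal(al2@aligned[, , 3], al@aligned[, , 3], tolerance = 1e-6,
               ignore_attr = TRUE)
  # degenerate configuration rejected
  line <- matrix(rep(1:26, 3), 26, 3,
                 dimnames = list(landmarkNames(defaultLandmarkDictionary()),
                                 NULL))
  expect_error(gpa(list(LandmarkSet(line), LandmarkSet(line))), "degenerate")
})
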