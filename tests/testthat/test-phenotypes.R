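test_that("angles: right angle, straight angle, 7800 count, 180-degree sums", {
  dict <- defaultLandmarkDictionary()
  set.seed(7)
  m <- matrix(rnorm(78, sd = 20), 26, 3,
              dimnames = list(landmarkNames(dict), NULL))
  m[1, ] <- c(0, 0, 0); m[2, ] <- c(1, 0, 0); m[3, ] <- c(0, 1, 0)
  m[4, ] <- c(-2, 0, 0)  # collinear with 1 and 2, vertex 1 in the middle
  lms <- LandmarkSet(m)
  ang <- angleMeasurements(lms)
  expect_length(ang, 7800L)
  n1 <- landmarkNames(dict)[1]; n2 <- landmarkNames(dict)[2]
  n3 <- landmarkNames(dict)[3]; n4 <- landmarkNames(dict)[4]
  expect_equal(unname(ang[paste0(n1, "-", n2, "-", n3, "@", n1)]), 90)
  expect_equal(unname(ang[paste0(n1, "-", n2, "-", n4, "@", n1)]), 180)
  expect_true(all(ang >= 0 & ang <= 180))
  sums <- rowSums(matrix(ang, ncol = 3, byrow = TRUE))
  expect_equal(sums, rep(180, 2600), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("coincident landmarks yield NA angles for the affected triples", {
  dict <- defaultLandmarkDictionary()
  m <- matrix(rnorm(78), 26, 3, dimnames = list(landmarkNames(dict), NULL))
  m[2, ] <- m[1, ]
  ang <- suppressWarnings(angleMeasurements(LandmarkSet(m)))
  # every triple containing both coincident points is NA
  bad <- grepl(paste0("(^|-)", landmarkNames(dict)[1], "(-|@)"), names(ang)) &
    grepl(paste0("(^|-)", landmarkNames(dict)[2], "(-|@)"), names(ang))
  expect_true(all(is.na(ang[bad])))
  expect_false(anyNA(ang[!bad]))
})

test_that("Heron areas equal the cross-product oracle on all 2600 triples", {
  dict <- defaultLandmarkDictionary()
  set.seed(8)
  m <- matrix(rnorm(78, sd = 15), 26, 3,
              dimnames = list(landmarkNames(dict), NULL))
  m[1, ] <- c(0, 0, 0); m[2, ] <- c(3, 0, 0); m[3, ] <- c(3, 4, 0)
  m[4, ] <- 0.5 * m[1, ] + 0.5 * m[2, ]   # collinear
  lms <- LandmarkSet(m)
  a <- triangleAreas(lms)
  expect_length(a, 2600L)
  expect_equal(unname(a[1]), 6)   # sides 3, 4, 5
  expect_equal(unname(a[paste(landmarkNames(dict)[c(1, 2, 4)],
                              collapse = "-")]), 0)
  tri <- t(combn(26, 3))
  cross_area <- vapply(seq_len(nrow(tri)), function(r) {
    u <- m[tri[r, 2], ] - m[tri[r, 1], ]
    w <- m[tri[r, 3], ] - m[tri[r, 1], ]
    cx <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sqrt(sum(cx^2)) / 2
  }, 0)
  expect_equal(unname(a), cross_area, tolerance = 1e-9)
})

test_that("proportion indices are min/max percentages with a 32-index default", {
  bat <- defaultIndexBattery()
  expect_equal(nrow(bat), 32L)
  d <- c("a-b" = 30, "c-d" = 40, "e-f" = 40)
  bat2 <- data.frame(name = c("i1", "i2"),
                     a1 = c("a", "c"), a2 = c("b", "d"),
                     b1 = c("c", "e"), b2 = c("d", "f"))
  idx <- proportionIndices(d, bat2)
  expect_equal(unname(idx), c(75, 100))
  expect_true(all(idx > 0 & idx <= 100))
  dz <- c("a-b" = 0, "c-d" = 0, "e-f" = 1)
  expect_error(proportionIndices(dz, bat2[1, ]), "zero denominator")
})

test_that("hull volumes and areas match unit solids and hull monotonicity", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  h <- convexHull3d(tetra)
  expect_equal(h$volume, 1 / 6, tolerance = 1e-12)
  expect_equal(h$area, 1.5 + sqrt(3) / 2, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  h2 <- convexHull3d(cube)
  expect_equal(h2$volume, 1, tolerance = 1e-12)
  expect_equal(h2$area, 6, tolerance = 1e-12)
  # interior points never change the hull
  set.seed(9)
  inner <- matrix(runif(30, 0.2, 0.8), 10, 3)
  h3 <- convexHull3d(rbind(cube, inner))
  expect_equal(h3$volume, 1, tolerance = 1e-12)
  expect_equal(h3$area, 6, tolerance = 1e-12)
  expect_warning(hf <- convexHull3d(cbind(runif(6), runif(6), 0)), "coplanar")
  expect_equal(hf$volume, 0)
})

test_that("region hull phenotypes cover the 10 default regions", {
  tpl <- small_template()
  lms <- templateLandmarks(tpl)
  rv <- regionVolumeSurface(lms)
  expect_equal(nrow(rv), 10L)
  expect_true(all(rv$volume > 0))
  expect_true(all(rv$surface_area > 0))
  expect_error(regionVolumeSurface(lms, list(bad = c("nope", "nasion"))),
               "nope")
})

test_that("the extracted library has the documented per-family counts", {
  tpl <- default_template()
  pop <- simulatePopulation(tpl, populationModel(), nPerRegion = 2, seed = 14)
  ph <- extractPhenotypes(pop)
  counts <- table(phenotypeCategories(ph))
  expect_equal(unname(counts["Point"]), 78L)
  expect_equal(unname(counts["Curvature"]), 52L)
  expect_equal(unname(counts["Euclidean"]), 325L)
  expect_equal(unname(counts["Manhattan"]), 325L)
  expect_equal(unname(counts["Geodesic"]), 325L)
  expect_equal(unname(counts["Index"]), 32L)
  expect_equal(unname(counts["Angle"]), 7800L)
  expect_equal(unname(counts["Triangle_area"]), 2600L)
  expect_equal(unname(counts["Volume"]), 10L)
  expect_equal(unname(counts["Surface_area"]), 10L)
  expect_true(all(phenotypeCategories(ph) %in% PHENOTYPE_CATEGORIES))
})
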