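test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroniThreshold(0.05, 14838), 3), 3.37e-6)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_true(all(diff(bonferroniThreshold(0.05, 1:100)) < 0))
})

test_that("region screen flags monotone phenotypes and handles constants", {
  g <- factor(rep(c("north", "central", "south"), each = 10),
              levels = c("north", "central", "south"))
  X <- cbind(mono = as.numeric(g) + 0, flat = rep(1, 30))
  expect_warning(scr <- regionScreen(X, g), "constant")
  expect_equal(scr$rho[1], 1)
  expect_equal(scr$label[1], "heterogeneous")
  expect_true(is.na(scr$p[2]))
  # kruskal mode agrees on the obvious call
  expect_warning(scr2 <- regionScreen(X, g, method = "kruskal"), "constant")
  expect_equal(scr2$label[1], "heterogeneous")
})

test_that("screen family-wise error is controlled under the global null", {
  set.seed(11)
  rej <- vapply(1:200, function(b) {
    X <- matrix(rnorm(90 * 200), 90)
    g <- factor(rep(c("n", "c", "s"), each = 30), levels = c("n", "c", "s"))
    any(regionScreen(X, g)$significant)
  }, TRUE)
  # FWER 0.05: binomial(200, 0.05) 99% upper band
  expect_lte(sum(rej), qbinom(0.995, 200, 0.05))
})

test_that("screen power: injected monotone effects at 5 SE are recovered", {
  set.seed(12)
  n1 <- 100; P <- 200; inj <- 1:20
  g <- factor(rep(c("n", "c", "s"), each = n1), levels = c("n", "c", "s"))
  X <- matrix(rnorm(3 * n1 * P), 3 * n1, P)
  # effect 5*SE per step of the ordinal coding
  se <- 1 / sqrt(n1)
  X[, inj] <- X[, inj] + (as.numeric(g) - 2) * 5 * se
  scr <- regionScreen(X, g)
  expect_gte(mean(scr$significant[inj]), 0.9)
  expect_lte(sum(scr$significant[-inj]), 3)
})

test_that("chi-square design balance matches the direct formula", {
  # perfectly proportional table: statistic 0, p 1
  bal <- chi2Balance(rbind(c(20, 40), c(10, 20), c(30, 60)))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  # 2x2 agrees with the exhaustive multinomial formula
  tab <- rbind(c(12, 34), c(25, 19))
  got <- chi2Balance(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(got$df, 1)
  expect_error(chi2Balance(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("PLS-DA satisfies the VIP identity and finds planted variables", {
  set.seed(13)
  n <- 200; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  g <- rep(c("a", "b"), each = n / 2)
  X[g == "b", 1:5] <- X[g == "b", 1:5] + 4
  m <- plsda(X, g, seed = 5)
  expect_equal(sum(vip(m)^2), length(vip(m)), tolerance = 1e-9)
  expect_setequal(order(-vip(m))[1:5], 1:5)
  expect_true(all(vip(m)[1:5] > 1))
  expect_lte(utils::tail(m@Q2, 1), utils::tail(m@R2Y, 1))
  expect_error(plsda(X, rep("a", n)), "2 groups")
  # scores/weights dimensions are coherent
  expect_equal(dim(m@scores), c(n, m@ncomp))
  expect_equal(dim(m@weights), c(p, m@ncomp))
})

test_that("PLS-DA cross-validated Q2 stays near zero under permuted labels", {
  q2 <- vapply(1:50, function(b) {
    set.seed(b)
    X <- matrix(rnorm(60 * 30), 60)
    g <- sample(rep(c("a", "b", "c"), each = 20))
    plsda(X, g, maxComp = 3, seed = b)@Q2[1]
  }, 0)
  expect_gte(mean(q2 <= 0.05), 0.95)
})

test_that("PLS-DA broadly agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(14)
  n <- 90; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  g <- rep(c("a", "b", "c"), each = 30)
  X[, 1] <- X[, 1] + c(-2, 0, 2)[as.integer(factor(g))]
  mine <- plsda(X, g, maxComp = 2, seed = 1)
  ref <- mixOmics::plsda(X, factor(g), ncomp = 2, scale = TRUE)
  # first-component X scores agree up to sign
  r <- abs(cor(mine@scores[, 1], ref$variates$X[, 1]))
  expect_gt(r, 0.99)
})

test_that("PERMANOVA reduces to one-way ANOVA in the univariate case", {
  set.seed(15)
  y <- rnorm(90)
  g <- rep(letters[1:3], each = 30)
  pv <- permanova(matrix(y), g, nPerm = 99, standardize = FALSE)
  a <- anova(stats::lm(y ~ g))
  expect_equal(pv$R2, a$`Sum Sq`[1] / sum(a$`Sum Sq`), tolerance = 1e-10)
  expect_equal(pv$F, a$`F value`[1], tolerance = 1e-10)
  expect_equal(permanova(matrix(y), g, nPerm = 999, seed = 1)$p >= 0.001, TRUE)
  expect_error(permanova(matrix(y), rep("a", 90)), "2 groups")
})

test_that("PERMANOVA matches vegan::adonis2 and is seed-reproducible", {
  skip_if_not_installed("vegan")
  set.seed(16)
  X <- matrix(rnorm(60 * 8), 60)
  g <- rep(c("a", "b", "c"), each = 20)
  pv <- permanova(X, g, nPerm = 199, seed = 3)
  ad <- vegan::adonis2(stats::dist(scale(X)) ~ g, permutations = 199)
  expect_equal(pv$R2, ad$R2[1], tolerance = 1e-10)
  expect_equal(pv$F, ad$F[1], tolerance = 1e-10)
  expect_identical(permanova(X, g, nPerm = 199, seed = 3)$p, pv$p)
})

test_that("PERMANOVA null p-values are uniform with E(R2) = (g-1)/(n-1)", {
  ps <- r2s <- numeric(200)
  for (b in 1:200) {
    set.seed(3000 + b)
    X <- matrix(rnorm(90 * 5), 90)
    pv <- permanova(X, rep(1:3, each = 30), nPerm = 199, seed = b)
    ps[b] <- pv$p; r2s[b] <- pv$R2
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(r2s), 2 / 89, tolerance = 0.2)
})

test_that("age adjustment is an idempotent projection orthogonal to age", {
  set.seed(17)
  n <- 120
  age <- round(runif(n, 20, 80))
  X <- cbind(indep = unname(stats::resid(stats::lm(rnorm(n) ~ age))),
             dep = 2 * age + rnorm(n))
  adj <- ageAdjust(X, age)
  expect_equal(adj[, "indep"], X[, "indep"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(abs(cor(adj[, "dep"], age)), 1e-10)
  expect_equal(ageAdjust(adj, age), adj, tolerance = 1e-10)
  expect_equal(colMeans(adj), colMeans(X), tolerance = 1e-10)
  expect_error(ageAdjust(X, rep(50, n)), "constant age")
})
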