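# PCA shape space and BCS regression.

surfMat <- function(v, n = 20) matrix(v, n, n)

test_that("identical surfaces give a zero-variance model: k = 0, null regression", {
  surfs <- replicate(6, surfMat(rep(3, 400)), simplify = FALSE)
  m <- fitShapeModel(surfs, bcs = c(2, 2.5, 3, 2.5, 2, 3))
  expect_equal(nComponents(m), 0L)
  expect_equal(coef(m), mean(c(2, 2.5, 3, 2.5, 2, 3)))
  expect_equal(predictBCS(surfs[[1]], m), mean(c(2, 2.5, 3, 2.5, 2, 3)))
  expect_error(fitPCA(surfs[1:2]), "at least 3")
})

test_that("a rank-1 family recovers its generating direction with fixed sign", {
  set.seed(21)
  u <- rnorm(400); u <- u / sqrt(sum(u^2))
  uCanon <- u * sign(u[which.max(abs(u))])  # package sign convention
  surfs <- lapply(seq(-4, 4, length.out = 9),
                  function(a) surfMat(10 + a * u))
  m <- fitPCA(surfs)
  expect_equal(nComponents(m), 1L)
  expect_lt(max(abs(shapeComponents(m)[1, ] - uCanon)), 1e-6)
  expect_gte(sum(explainedVariance(m)), 1 - 1e-9)
})

test_that("a planted 2-factor family yields k = 2 and the planted subspace", {
  set.seed(22)
  u1 <- rnorm(400); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(400); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  ab <- cbind(rnorm(40, sd = 3), rnorm(40, sd = 1.5))
  surfs <- lapply(1:40, function(i) surfMat(5 + ab[i, 1] * u1 + ab[i, 2] * u2))
  m <- fitPCA(surfs, varianceThreshold = 0.95)
  expect_equal(nComponents(m), 2L)
  # principal angles between fitted and planted subspaces below 5 degrees
  B <- t(shapeComponents(m))
  A <- cbind(u1, u2)
  sv <- svd(t(A) %*% B)$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("projection obeys orthonormality and the truncation optimality", {
  set.seed(23)
  surfs <- lapply(1:12, function(i) surfMat(rnorm(400)))
  m <- fitPCA(surfs, varianceThreshold = 0.999, kMax = 8)
  k <- nComponents(m)
  expect_gte(k, 3)
  C <- shapeComponents(m)
  expect_lt(max(abs(tcrossprod(C) - diag(k))), 1e-8)

  expect_equal(projectSurface(surfMat(meanSurface(m)), m), rep(0, k))
  v <- meanSurface(m) + 2 * C[1, ]
  expect_equal(projectSurface(surfMat(v), m), c(2, rep(0, k - 1)),
               tolerance = 1e-8)

  # Eckart-Young: residual norm decreases monotonically with truncation order
  x <- as.vector(surfs[[4]]) - meanSurface(m)
  sc <- as.numeric(C %*% x)
  resid <- vapply(0:k, function(j) {
    approx <- if (j == 0) rep(0, 400) else as.numeric(t(C[1:j, , drop = FALSE]) %*% sc[1:j])
    sqrt(sum((x - approx)^2))
  }, numeric(1))
  expect_true(all(diff(resid) < 1e-12))
})

test_that("fitRegression: exact interpolation, recovery at n = 200, edge cases", {
  set.seed(24)
  s <- matrix(rnorm(40), 20, 2)
  bcs <- 2.5 + 0.3 * s[, 1] - 0.1 * s[, 2]
  cf <- fitRegression(s, bcs)
  expect_lt(max(abs(s %*% cf[-1] + cf[1] - bcs)), 1e-9)

  s2 <- matrix(rnorm(400), 200, 2)
  bcs2 <- 2.5 + 0.3 * s2[, 1] - 0.1 * s2[, 2] + rnorm(200, sd = 0.1)
  cf2 <- fitRegression(s2, bcs2)
  expect_lt(max(abs(cf2 - c(2.5, 0.3, -0.1))), 0.05)

  expect_error(fitRegression(matrix(rnorm(4), 2, 2), c(1, 2)), "n > k")
})

test_that("prediction interpolates a noiseless affine generative model", {
  set.seed(25)
  u1 <- rnorm(400); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(400); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  a <- rnorm(30); b <- rnorm(30)
  bcs <- 2.6 + 0.25 * a - 0.15 * b
  surfs <- lapply(1:30, function(i) surfMat(4 + a[i] * u1 + b[i] * u2))
  m <- fitShapeModel(surfs, bcs)
  preds <- vapply(surfs, predictBCS, numeric(1), model = m)
  expect_lt(max(abs(preds - bcs)), 1e-6)
  expect_equal(predictBCS(surfMat(meanSurface(m)), m), coef(m)[1])
  # clipping at the API boundary
  extreme <- surfMat(4 + 1e4 * u1)
  expect_gte(predictBCS(extreme, m), 0)
  expect_lte(predictBCS(extreme, m), 5)
})

test_that("evaluateRMSEP matches hand arithmetic", {
  expect_equal(evaluateRMSEP(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(evaluateRMSEP(rep(3, 7), rep(2.5, 7)), 0.5)
  expect_equal(evaluateRMSEP(c(0.3, -0.4), c(0, 0)), sqrt(0.25 / 2))
  expect_equal(round(evaluateRMSEP(c(0.3, -0.4), c(0, 0)), 4), 0.3536)
  expect_error(evaluateRMSEP(1:3, 1:4), "equal length")
})

test_that("fitting is bit-deterministic and ignores zero-variance borders", {
  set.seed(26)
  surfs <- lapply(1:15, function(i) surfMat(rnorm(400) + i / 10))
  bcs <- runif(15, 2, 3.5)
  m1 <- fitShapeModel(surfs, bcs)
  m2 <- fitShapeModel(surfs, bcs)
  expect_identical(shapeComponents(m1), shapeComponents(m2))
  expect_identical(coef(m1), coef(m2))

  pad <- function(g) { out <- matrix(0, 22, 22); out[2:21, 2:21] <- g; out }
  mP <- fitShapeModel(lapply(surfs, pad), bcs)
  s1 <- vapply(surfs, projectSurface, numeric(nComponents(m1)), model = m1)
  sP <- vapply(lapply(surfs, pad), projectSurface,
               numeric(nComponents(mP)), model = mP)
  expect_equal(nComponents(mP), nComponents(m1))
  expect_lt(max(abs(abs(s1) - abs(sP))), 1e-9)
})

test_that("model persistence round trips and detects tampering", {
  set.seed(27)
  surfs <- lapply(1:10, function(i) surfMat(rnorm(400)))
  bcs <- runif(10, 2, 3.5)
  m <- fitShapeModel(surfs, bcs, kMax = 5L)
  path <- file.path(tempdir(), "model.bcs3d")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(meanSurface(back), meanSurface(m))
  expect_identical(shapeComponents(back), shapeComponents(m))
  expect_identical(coef(back), coef(m))
  probe <- surfMat(rnorm(400))
  expect_identical(predictBCS(probe, back), predictBCS(probe, m))

  # flip one byte in the array section: checksum must catch it
  raw <- readBin(path, "raw", n = file.size(path))
  raw[length(raw) - 5] <- as.raw(bitwXor(as.integer(raw[length(raw) - 5]), 255L))
  tam <- file.path(tempdir(), "tampered.bcs3d")
  writeBin(raw, tam)
  expect_error(loadModel(tam), "checksum")
  writeLines("junk", tam)
  expect_error(loadModel(tam), "not a shape model")
})
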