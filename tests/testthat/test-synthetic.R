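# Synthetic dorsal-surface generator.

test_that("the BCS-to-geometry map is affine, monotone and zero at BCS 5", {
  expect_equal(unname(prominences(defaultFatness(5))), rep(0, 4))
  p2 <- prominences(defaultFatness(2))
  p3 <- prominences(defaultFatness(3))
  expect_true(all(p2 > p3))
  expect_true(any(p2 - p3 >= 5))   # a whole point of BCS is clearly visible
  # documented affine formulas evaluated by hand at 2.58
  p <- prominences(defaultFatness(2.58))
  expect_equal(unname(p), c(12 - 2.4 * 2.58, 15 - 3 * 2.58,
                            10 - 2 * 2.58, 25 - 5 * 2.58))
  expect_error(defaultFatness(5.2), "0, 5")
  expect_error(defaultFatness(-0.1), "0, 5")
})

test_that("generateSurface is deterministic and validates morphology", {
  s1 <- generateSurface(defaultFatness(2.5), seed = 7)
  s2 <- generateSurface(defaultFatness(2.5), seed = 7)
  expect_identical(cloudPoints(s1), cloudPoints(s2))
  s3 <- generateSurface(defaultFatness(2.5), seed = 8)
  expect_false(identical(cloudPoints(s1), cloudPoints(s3)))
  expect_error(generateSurface(defaultFatness(2.5),
                               defaultMorphology(hip_width = -10)),
               "positive")
})

test_that("at BCS 5 the surface is the bare quadric base cap", {
  m <- defaultMorphology()
  f5 <- defaultFatness(5)
  gx <- seq(-300, 300, length.out = 41)
  gy <- seq(-50, 440, length.out = 41)
  pts <- expand.grid(x = gx, y = gy)
  z <- dorsalHeight(pts$x, pts$y, f5, m)
  # all features have zero amplitude: a quadratic in (x, y) fits exactly
  fit <- lm(z ~ poly(x, 2, raw = TRUE) + poly(y, 2, raw = TRUE), data = pts)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("the surface is mirror symmetric for symmetric morphology", {
  f <- defaultFatness(2.3)
  x <- seq(10, 310, by = 25)
  y <- seq(-40, 430, by = 37)
  g <- expand.grid(x = x, y = y)
  zl <- dorsalHeight(-g$x, g$y, f)
  zr <- dorsalHeight(g$x, g$y, f)
  expect_equal(zl, zr, tolerance = 1e-12)
  lm <- landmarkCoords(generateSurface(f, seed = 1))
  expect_lt(abs(lm["left_ischium", 3] - lm["right_ischium", 3]), 1e-9)
  expect_lt(abs(lm["left_sacrum", 3] - lm["right_sacrum", 3]), 1e-9)
})

test_that("true landmarks are mesh vertices and encode the hip width", {
  morph <- defaultMorphology(hip_width = 480)
  pose <- list(rotation = rotZ(0.2) %*% rotX(0.05), translation = c(15, -20, 4))
  sc <- generateSurface(defaultFatness(2.8), morph, seed = 3, pose = pose)
  pts <- cloudPoints(sc)
  lm <- landmarkCoords(sc)
  for (i in 1:4) {
    d <- sqrt(colSums((t(pts) - lm[i, ])^2))
    expect_lt(min(d), 1e-9)  # coincide with designated vertices
  }
  sep <- sqrt(sum((lm["left_ischium", ] - lm["right_ischium", ])^2))
  expect_equal(sep, 480, tolerance = 1e-6)
  expect_gte(nrow(pts), 1e4)
})

test_that("corruptDepth: identity, binomial dropout and noise sd are as declared", {
  fx <- sceneFixture(2.5, seed = 2)
  d <- fx$depth
  expect_identical(depthValues(corruptDepth(d, 0, 0, seed = 1)), depthValues(d))

  nv <- sum(validMask(d))
  expect_gt(nv, 1e4)
  dd <- corruptDepth(d, 0, 0.5, seed = 3)
  kept <- sum(validMask(dd))
  # binomial 3 sigma around nv/2 (spec bound scaled to the actual pixel count)
  expect_lt(abs(kept - nv / 2), 3 * sqrt(nv * 0.25) + 1)

  dn <- corruptDepth(d, 3, 0, seed = 4)
  delta <- depthValues(dn)[validMask(d)] - depthValues(d)[validMask(d)]
  expect_gt(stats::sd(delta), 2.8)
  expect_lt(stats::sd(delta), 3.2)

  expect_error(corruptDepth(d, -1, 0), "noiseSd")
  expect_error(corruptDepth(d, 0, 1), "dropoutFrac")
})

test_that("normalized-surface curvature decreases strictly with BCS", {
  curv <- vapply(c(1, 2, 3, 4, 5), function(b) {
    fx <- sceneFixture(b, seed = 11)
    surf <- processDepth(fx$depth, landmarks = fx$truthCam)
    g <- surfaceGrid(surf)
    n <- nrow(g)
    lap <- g[2:(n - 1), 2:(n - 1)] * 4 - g[1:(n - 2), 2:(n - 1)] -
      g[3:n, 2:(n - 1)] - g[2:(n - 1), 1:(n - 2)] - g[2:(n - 1), 3:n]
    mean(abs(lap))
  }, numeric(1))
  expect_true(all(diff(curv) < 0))
})
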