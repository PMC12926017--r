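# Canonical frame and ROI resampling.

test_that("computeFrame fixes canonical-pose landmarks and inverts rigid moves", {
  lm <- canonicalLandmarks()
  fr <- computeFrame(lm)
  expect_equal(frameRotation(fr), diag(3), tolerance = 1e-9)
  expect_equal(frameTranslation(fr), rep(0, 3), tolerance = 1e-9)
  expect_equal(det(frameRotation(fr)), 1, tolerance = 1e-9)

  R <- rotZ(0.31) %*% rotX(0.12) %*% rotY(-0.07)
  tr <- c(120, -340, 55)
  moved <- LandmarkSet(transformPoints(landmarkCoords(lm), R, tr))
  fr2 <- computeFrame(moved)
  restored <- applyFrame(fr2, landmarkCoords(moved))
  expect_equal(restored, landmarkCoords(lm), tolerance = 1e-9)
})

test_that("computeFrame maps a hand-built quadruple to x-symmetric positions", {
  co <- rbind(left_ischium  = c(-100, 0, 0),
              right_ischium = c(100, 0, 0),
              left_sacrum   = c(-60, 180, 10),
              right_sacrum  = c(60, 180, 10))
  lm <- LandmarkSet(co)
  fr <- computeFrame(lm)
  mapped <- applyFrame(fr, co)
  # direct matrix arithmetic oracle: x = e1, y = unit(0, 180, 10), z = x cross y
  ctr <- colMeans(co)
  yh <- c(0, 180, 10) / sqrt(180^2 + 10^2)
  Rora <- rbind(c(1, 0, 0), yh, c(0, -yh[3], yh[2]))
  expect_equal(unname(mapped), unname(t(Rora %*% (t(co) - ctr))), tolerance = 1e-12)
  expect_equal(unname(mapped[1, 1]), -unname(mapped[2, 1]),
               tolerance = 1e-9)   # x-symmetric ischia
  expect_equal(colMeans(mapped), rep(0, 3), tolerance = 1e-9)   # zero-mean centroid
})

test_that("collinear landmarks raise a degenerate-geometry error", {
  co <- rbind(left_ischium  = c(-100, 0, 0),
              right_ischium = c(100, 0, 0),
              left_sacrum   = c(-50, 0, 0),
              right_sacrum  = c(50, 0, 0))
  expect_error(computeFrame(LandmarkSet(co)), "collinear")
})

test_that("a constant plane resamples to constant heights with full validity", {
  lm <- canonicalLandmarks()
  set.seed(5)
  xy <- cbind(runif(6000, -320, 320), runif(6000, -120, 120))
  cloud <- PointCloud(cbind(xy, 5), frame = "world")
  surf <- extractROI(cloud, roiFrame(lm))
  expect_equal(dim(surfaceGrid(surf)), c(150L, 150L))
  expect_equal(validFraction(surf), 1)
  expect_lt(max(abs(surfaceGrid(surf) - 5)), 1e-6)
  # physical extent is recorded, not normalized away
  expect_equal(unname(scaleRecord(surf)["width_mm"]), 500 * 1.2)
  expect_equal(unname(scaleRecord(surf)["length_mm"]), 160 * 1.2)
})

test_that("an emptied ROI is a degenerate input", {
  lm <- canonicalLandmarks()
  set.seed(6)
  far <- cbind(runif(5000, 2000, 3000), runif(5000, 2000, 3000), 0)
  expect_error(extractROI(PointCloud(far, frame = "world"), roiFrame(lm)),
               "ROI")
})

test_that("scale honesty: hip width changes the scale record, not the grid size", {
  fx1 <- sceneFixture(2.5, seed = 9)
  s1 <- processDepth(fx1$depth, landmarks = fx1$truthCam)
  sc2 <- generateSurface(defaultFatness(2.5),
                         defaultMorphology(hip_width = 560), seed = 9)
  pp <- defaultCameraPose()
  truth2 <- LandmarkSet(transformPoints(landmarkCoords(sc2), pp$rotation,
                                        -as.numeric(pp$rotation %*% pp$center)))
  s2 <- processDepth(renderDepth(sc2), landmarks = truth2)
  expect_equal(dim(surfaceGrid(s1)), dim(surfaceGrid(s2)))
  expect_gt(scaleRecord(s2)[["width_mm"]], scaleRecord(s1)[["width_mm"]] + 40)
})

test_that("imputeSurface: identity, harmonic fill of a plane, quality floor", {
  lm <- canonicalLandmarks()
  set.seed(7)
  xy <- cbind(runif(8000, -320, 320), runif(8000, -120, 120))
  plane <- PointCloud(cbind(xy, 0.02 * xy[, 1] + 5), frame = "world")
  surf <- extractROI(plane, roiFrame(lm))
  expect_identical(surfaceGrid(imputeSurface(surf)), surfaceGrid(surf))

  # exact affine field: the harmonic fill restores the plane value
  xs <- seq(0, 149) * 4; ys <- seq(0, 149) * 1.2
  gA <- outer(ys, xs, function(y, x) 5 + 0.02 * x - 0.01 * y)
  vA <- matrix(TRUE, 150, 150)
  gH <- gA; vH <- vA
  gH[75, 80] <- NA; vH[75, 80] <- FALSE
  holed <- new("NormalizedSurface", grid = gH, valid = vH,
               scaleRecord = scaleRecord(surf), roi = surf@roi)
  filled <- imputeSurface(holed)
  expect_lt(abs(surfaceGrid(filled)[75, 80] - gA[75, 80]), 1e-6)
  expect_false(validMask(filled)[75, 80])  # audit mask preserved

  g <- surfaceGrid(surf); v <- validMask(surf)
  vBad <- v; vBad[, 1:75] <- FALSE
  gBad <- g; gBad[, 1:75] <- NA
  low <- new("NormalizedSurface", grid = gBad, valid = vBad,
             scaleRecord = scaleRecord(surf), roi = surf@roi)
  expect_error(imputeSurface(low), "valid fraction")
})

test_that("normalized grids are invariant to body pose (noiseless)", {
  base <- NULL
  set.seed(12)
  for (i in 0:2) {
    pose <- if (i == 0) list(rotation = diag(3), translation = c(0, 0, 0))
    else list(rotation = rotZ(runif(1, -15, 15) * pi / 180) %*%
                rotX(runif(1, -5, 5) * pi / 180),
              translation = c(runif(2, -30, 30), 0))
    fx <- sceneFixture(2.5, seed = 5, pose = pose)
    surf <- processDepth(fx$depth, landmarks = fx$truthCam)
    g <- surfaceGrid(surf)
    if (i == 0) base <- g
    else expect_lt(sqrt(mean((g - base)^2)), 1)
  }
})
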