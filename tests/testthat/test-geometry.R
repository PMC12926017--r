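# Camera model, stereo matching, triangulation and back-projection.

test_that("disparityToDepth follows z = fx b / d with sentinel handling", {
  cam <- testCamera()
  disp <- matrix(c(33, 0, 66, NA), 2, 2)
  d <- disparityToDepth(disp, cam)
  expect_equal(depthValues(d)[1, 1], 600 * 55 / 33)  # 1000 mm
  expect_equal(depthValues(d)[1, 1], 1000)
  expect_false(validMask(d)[2, 1])                   # disparity 0: invalid
  expect_false(validMask(d)[2, 2])
  # halving disparity doubles depth
  expect_equal(depthValues(d)[1, 2], depthValues(d)[1, 1] / 2)
  camMono <- CameraIntrinsics(600, 600, 320, 240, 640, 480, 0)
  expect_error(disparityToDepth(disp, camMono), "baseline")
})

test_that("depthToPointCloud back-projects through the pinhole model", {
  cam <- testCamera()
  vals <- matrix(0, 480, 640)
  vals[240 + 1, 320 + 1] <- 800   # pixel (u=cx, v=cy), 0-based
  vals[240 + 1, 320 + 300 + 1] <- 500  # u = cx + fx/2
  d <- DepthMap(vals, intrinsics = cam)
  pts <- cloudPoints(depthToPointCloud(d))
  expect_equal(nrow(pts), 2)
  i0 <- which(pts[, 3] == 800)
  expect_equal(unname(pts[i0, ]), c(0, 0, 800))
  i1 <- which(pts[, 3] == 500)
  expect_equal(unname(pts[i1, 1]), 250)  # x = (u - cx) z / fx = 300*500/600
})

test_that("a constant-depth plane back-projects to a plane (fit RMS < 1e-6)", {
  cam <- testCamera()
  vals <- matrix(1000, 480, 640)
  pts <- cloudPoints(depthToPointCloud(DepthMap(vals, intrinsics = cam)))
  # plane fit via SVD of the centred coordinates
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 3)
  normal <- sv$v[, 3]
  res <- as.numeric(sweep(pts, 2, ctr) %*% normal)
  expect_lt(sqrt(mean(res^2)), 1e-6)
})

test_that("back-projection then re-projection restores pixel centres", {
  cam <- testCamera()
  set.seed(4)
  vals <- matrix(0, 480, 640)
  idx <- sample(480 * 640, 500)
  vals[idx] <- runif(500, 500, 3000)
  d <- DepthMap(vals, intrinsics = cam)
  pts <- cloudPoints(depthToPointCloud(d))
  uv <- projectPoints(pts, cam)
  iv <- (which(validMask(d)) - 1) %% 480
  iu <- (which(validMask(d)) - 1) %/% 480
  expect_lt(max(abs(uv[, "u"] - iu)), 1e-6)
  expect_lt(max(abs(uv[, "v"] - iv)), 1e-6)
})

test_that("block matching recovers a pure shift and a zero shift", {
  set.seed(11)
  L <- matrix(runif(120 * 90), 90, 120)
  R <- cbind(L[, 8:120], matrix(runif(90 * 7), 90, 7))  # right = left shifted by 7
  disp <- findDisparity(L, R, window = 7, maxDisp = 20)
  interior <- disp[10:80, 20:100]
  expect_true(all(interior == 7, na.rm = TRUE))
  disp0 <- findDisparity(L, L, window = 7, maxDisp = 20)
  expect_true(all(disp0[10:80, 20:100] == 0, na.rm = TRUE))
  expect_error(findDisparity(L, R[, 1:100], 7, 20), "dimensions")
  expect_error(findDisparity(L, R, 4, 20), "odd")
})

test_that("disparity of a rendered textured two-plane scene matches fx b / z", {
  cam <- testCamera()
  # two fronto-parallel textured planes rendered at two camera positions a
  # baseline apart: analytic disparity is fx b / z per plane (33 and 22 px)
  set.seed(21)
  nr <- 100; nc <- 220
  z <- rep(1000, nc); z[111:nc] <- 1100  # disparities 33 and 30 px
  L <- matrix(runif(nr * nc), nr, nc)    # textured left view
  R <- matrix(runif(nr * nc), nr, nc)    # disoccluded right pixels stay noise
  dCol <- round(cam@fx * cam@baseline / z)
  for (j in 1:nc) {
    jr <- j - dCol[j]                    # the same world point, right view
    if (jr >= 1 && jr <= nc) R[, jr] <- L[, j]
  }
  disp <- findDisparity(L, R, window = 9, maxDisp = 45)
  dTrue <- matrix(rep(dCol, each = nr), nr, nc)
  interior <- cbind(as.vector(disp[10:90, 40:200]), as.vector(dTrue[10:90, 40:200]))
  ok <- abs(interior[, 1] - interior[, 2]) <= 1
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("renderDepth projects points onto the expected pixels", {
  cam <- testCamera()
  pose <- list(rotation = diag(3), center = c(0, 0, 0))  # camera at origin, +z fwd
  d <- renderDepth(matrix(c(0, 0, 1000), 1, 3), cam, pose)
  expect_equal(depthValues(d)[240 + 1, 320 + 1], 1000)
  expect_equal(sum(validMask(d)), 1)
  # doubling camera height above a flat plane adds the height change
  plane <- as.matrix(expand.grid(x = seq(-300, 300, 10), y = seq(-300, 300, 10)))
  plane <- cbind(plane, z = 0)
  pp1 <- list(rotation = diag(c(1, -1, -1)), center = c(0, 0, 1000))
  pp2 <- list(rotation = diag(c(1, -1, -1)), center = c(0, 0, 2000))
  d1 <- renderDepth(plane, cam, pp1)
  d2 <- renderDepth(plane, cam, pp2)
  common <- validMask(d1) & validMask(d2)
  expect_true(all(abs(depthValues(d2)[common] - depthValues(d1)[common] - 1000) < 1e-9))
  # camera looking away from every point: empty-map error
  expect_error(renderDepth(matrix(c(0, 0, -10), 1, 3), cam, pose), "behind|projects")
})

test_that("a rendered scene round-trips to the analytic surface within 2 mm RMS", {
  fx <- sceneFixture(2.5, seed = 6)
  cl <- cameraToWorld(depthToPointCloud(fx$depth), defaultCameraPose())
  pts <- cloudPoints(cl)
  zTrue <- dorsalHeight(pts[, 1], pts[, 2], fatness(fx$scene),
                        morphology(fx$scene))
  expect_lt(sqrt(mean((pts[, 3] - zTrue)^2)), 2)
})
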