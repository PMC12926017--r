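# Shared fixtures, built in code. A small cache avoids re-rendering the same
# synthetic scene across test files.

.fixtures <- new.env(parent = emptyenv())

testCamera <- function() CameraIntrinsics(600, 600, 320, 240, 640, 480, 55)

# scene + (optionally corrupted) depth frame + camera-frame truth landmarks
sceneFixture <- function(bcs = 2.5, seed = 1, noiseSd = 0, dropout = 0,
                         pose = list(rotation = diag(3), translation = c(0, 0, 0))) {
  key <- paste("scene", bcs, seed, noiseSd, dropout,
               signif(sum(pose$rotation * (1:9)), 10),
               paste(signif(pose$translation, 8), collapse = ","), sep = "|")
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  sc <- generateSurface(defaultFatness(bcs), seed = seed, pose = pose)
  d <- renderDepth(sc)
  if (noiseSd > 0 || dropout > 0)
    d <- corruptDepth(d, noiseSd, dropout, seed = seed + 5000)
  pp <- defaultCameraPose()
  truthCam <- LandmarkSet(transformPoints(
    landmarkCoords(sc), pp$rotation, -as.numeric(pp$rotation %*% pp$center)))
  out <- list(scene = sc, depth = d, truthCam = truthCam)
  .fixtures[[key]] <- out
  out
}

# hand-built landmark quadruple already in canonical pose:
# ischia on the x axis, sacra anterior, centroid at the origin
canonicalLandmarks <- function(halfWidth = 250, sacY = 160, sacHalf = 90) {
  co <- rbind(left_ischium  = c(-halfWidth, -sacY / 2, 0),
              right_ischium = c(halfWidth, -sacY / 2, 0),
              left_sacrum   = c(-sacHalf, sacY / 2, 0),
              right_sacrum  = c(sacHalf, sacY / 2, 0))
  LandmarkSet(co)
}

# independent brute-force weighted least squares for the LOESS oracle
wlsOracleFit <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  d <- abs(x - x0)
  idx <- order(d, x)[seq_len(q)]
  dmax <- d[idx[q]]
  if (dmax <= 0) return(mean(y[idx]))
  w <- (1 - pmin(1, d[idx] / dmax)^3)^3
  X <- outer(x[idx] - x0, 0:degree, `^`)
  fit <- stats::lm.wfit(X, y[idx], w)
  unname(fit$coefficients[1])
}
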