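## Synthetic heifer dorsal surfaces.
##
## The dorsal hips-to-pins region is modelled as a smooth quadric base cap plus
## localized Gaussian features, each scaled by one fatness parameter:
##   base(x, y)  = -cx x^2 - cy (y - yc)^2                  (body rounding)
##   + spine      ridge along the midline (constant in y)
##   + pins       two bumps at (+-hw/2, 0)                  (ischia; landmarks)
##   + sacra      two bumps at (+-0.36 hw / 2 scaled, 0.35 L)  (landmarks)
##   + hooks      two bumps at (+-0.55 hw, 0.8 L)           (hip bones)
##   - tail       one depression at (0, 0.16 L)             (tail head)
## Coordinates: x lateral (animal-left negative), y longitudinal (posterior at
## the pins, anterior positive), z dorsal height, all mm. Every feature is an
## analytic Gaussian so landmark positions, symmetry and curvature have closed
## forms that oracle tests can use.

.synth <- list(
  base_drop_x   = 15,    # mm drop of the base cap at x = 0.6 * hip width
  base_x_frac   = 0.6,
  base_drop_y   = 12,    # mm drop of the base cap at |y - yc| = 225 mm
  base_y_scale  = 225,
  yc_frac       = 0.13,  # base cap apex, fraction of body length
  spine_sigma   = 30,
  pin_sigma     = c(x = 15, y = 12),
  sac_sigma     = c(x = 14, y = 10),
  sac_w_frac    = 0.36,  # sacral landmark separation, fraction of hip width
  sac_y_frac    = 0.35,  # sacral landmark station, fraction of body length
  sac_amp_frac  = 0.8,   # sacral amplitude as a fraction of hook prominence
  hook_sigma    = c(x = 20, y = 18),
  hook_x_frac   = 0.55,
  hook_y_frac   = 0.8,
  tail_sigma    = c(x = 28, y = 26),
  tail_y_frac   = 0.16,
  dom_x_frac    = 0.63,  # mesh domain: |x| <= 0.63 * hip width
  dom_y_frac    = c(-0.12, 1.0),
  mesh_n        = 160L
)

#' Default mapping from BCS to fatness geometry
#'
#' Affine, strictly decreasing maps from the 0-5 BCS scale to bony prominence
#' heights, all reaching exactly 0 mm at BCS 5 (a maximally fat, fully smooth
#' back):
#' \deqn{spine = 12 - 2.4 b,\; hook = 15 - 3 b,\; pin = 10 - 2 b,\;
#'       tail = 25 - 5 b \quad (mm),}
#' clipped at 0. Adjacent whole scores (e.g. 2 vs 3) differ by 5 mm in the
#' tail-head depression, the most visible feature.
#'
#' @param bcsTrue score in `[0, 5]`.
#' @return a [FatnessParams-class].
#' @export
defaultFatness <- function(bcsTrue) {
  if (!isScalarNumber(bcsTrue) || bcsTrue < 0 || bcsTrue > 5)
    bcsStop("invalidArgument", "bcsTrue must be a number in [0, 5]")
  FatnessParams(bcsTrue = bcsTrue,
                spineProminence     = max(0, 12 - 2.4 * bcsTrue),
                hookProminence      = max(0, 15 - 3.0 * bcsTrue),
                pinProminence       = max(0, 10 - 2.0 * bcsTrue),
                tailDepressionDepth = max(0, 25 - 5.0 * bcsTrue))
}

#' Default heifer morphology
#'
#' Body dimensions (mm) default to the herd averages of the packaged heifer
#' table: hip width (here the ischium landmark separation) 507 mm, withers
#' height 1376 mm; body length of the modelled hips-to-pins patch 450 mm.
#'
#' @param hip_width,body_length,withers_height mm.
#' @return a named list.
#' @export
defaultMorphology <- function(hip_width = 507, body_length = 450,
                              withers_height = 1376) {
  if (hip_width <= 0 || body_length <= 0 || withers_height <= 0)
    bcsStop("invalidArgument", "morphology dimensions must be positive")
  list(hip_width = hip_width, body_length = body_length,
       withers_height = withers_height)
}

#' Analytic height of the synthetic dorsal surface
#'
#' Evaluates the parametric surface at arbitrary planar coordinates; used both
#' by the generator and as the closed-form oracle in tests.
#'
#' @param x,y numeric vectors, mm (generator frame: pins at y = 0).
#' @param fatness a [FatnessParams-class].
#' @param morphology a morphology list, see [defaultMorphology()].
#' @return numeric vector of heights, mm.
#' @export
dorsalHeight <- function(x, y, fatness, morphology = defaultMorphology()) {
  s <- .synth
  hw <- morphology$hip_width
  L  <- morphology$body_length
  yc <- s$yc_frac * L
  cx <- s$base_drop_x / (s$base_x_frac * hw)^2
  cy <- s$base_drop_y / s$base_y_scale^2
  g2 <- function(dx, dy, sig) exp(-(dx^2 / (2 * sig[["x"]]^2) +
                                    dy^2 / (2 * sig[["y"]]^2)))
  z <- -cx * x^2 - cy * (y - yc)^2 +
    fatness@spineProminence * exp(-x^2 / (2 * s$spine_sigma^2)) +
    fatness@pinProminence  * (g2(x - hw / 2, y, s$pin_sigma) +
                              g2(x + hw / 2, y, s$pin_sigma)) +
    s$sac_amp_frac * fatness@hookProminence *
      (g2(x - s$sac_w_frac * hw / 2, y - s$sac_y_frac * L, s$sac_sigma) +
       g2(x + s$sac_w_frac * hw / 2, y - s$sac_y_frac * L, s$sac_sigma)) +
    fatness@hookProminence * (g2(x - s$hook_x_frac * hw, y - s$hook_y_frac * L, s$hook_sigma) +
                              g2(x + s$hook_x_frac * hw, y - s$hook_y_frac * L, s$hook_sigma)) -
    fatness@tailDepressionDepth * g2(x, y - s$tail_y_frac * L, s$tail_sigma)
  z
}

# Generator-frame landmark positions (4 x 3), rows in LandmarkSet order.
.trueLandmarkPositions <- function(fatness, morphology) {
  s <- .synth
  hw <- morphology$hip_width
  L  <- morphology$body_length
  xy <- rbind(left_ischium  = c(-hw / 2, 0),
              right_ischium = c(+hw / 2, 0),
              left_sacrum   = c(-s$sac_w_frac * hw / 2, s$sac_y_frac * L),
              right_sacrum  = c(+s$sac_w_frac * hw / 2, s$sac_y_frac * L))
  cbind(xy, z = dorsalHeight(xy[, 1], xy[, 2], fatness, morphology))
}

#' Generate a synthetic dorsal scene
#'
#' Samples the analytic surface on a jittered regular mesh (>= 10^4 points),
#' appends the four ground-truth landmark vertices exactly, and applies the
#' body pose. Deterministic for fixed arguments.
#'
#' @param fatness a [FatnessParams-class].
#' @param morphology a morphology list, see [defaultMorphology()].
#' @param seed integer seed for the mesh jitter.
#' @param pose list with `rotation` (3 x 3) and `translation` (numeric(3));
#'   identity by default.
#' @return a [SyntheticScene-class].
#' @export
generateSurface <- function(fatness, morphology = defaultMorphology(),
                            seed = 0L,
                            pose = list(rotation = diag(3),
                                        translation = c(0, 0, 0))) {
  stopifnot(is(fatness, "FatnessParams"))
  if (any(unlist(morphology[c("hip_width", "body_length", "withers_height")]) <= 0))
    bcsStop("invalidArgument", "morphology dimensions must be positive")
  s <- .synth
  hw <- morphology$hip_width
  L  <- morphology$body_length
  n  <- s$mesh_n
  gx <- seq(-s$dom_x_frac * hw, s$dom_x_frac * hw, length.out = n)
  gy <- seq(s$dom_y_frac[1] * L, s$dom_y_frac[2] * L, length.out = n)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  xy <- cbind(rep(gx, times = n), rep(gy, each = n))
  jit <- withSeed(deriveSeed(seed, 0L), {
    matrix(stats::runif(2L * n * n, -0.35, 0.35), ncol = 2)
  })
  xy[, 1] <- xy[, 1] + jit[, 1] * dx
  xy[, 2] <- xy[, 2] + jit[, 2] * dy
  z <- dorsalHeight(xy[, 1], xy[, 2], fatness, morphology)
  lm <- .trueLandmarkPositions(fatness, morphology)
  pts <- rbind(cbind(xy, z), unname(lm))
  pts <- transformPoints(pts, pose$rotation, pose$translation)
  lmw <- transformPoints(lm, pose$rotation, pose$translation)
  new("SyntheticScene", points = pts,
      landmarks = LandmarkSet(lmw),
      fatness = fatness, pose = pose, morphology = morphology)
}

#' Default overhead camera
#'
#' RealSense-like intrinsics: fx = fy = 600 px, 640 x 480, baseline 55 mm.
#' These are configuration values of the simulated rig, not device claims.
#'
#' @param fx,fy,cx,cy,width,height,baseline see [CameraIntrinsics()].
#' @export
defaultCamera <- function(fx = 600, fy = 600, cx = 319.5, cy = 239.5,
                          width = 640, height = 480, baseline = 55) {
  CameraIntrinsics(fx, fy, cx, cy, width, height, baseline)
}

#' Default camera extrinsics
#'
#' Optical centre `height` mm above the generator origin, `forward` mm
#' anterior, looking straight down. The rotation maps world to camera axes
#' (`x_c = x_w`, `y_c = -y_w`, `z_c = -z_w`), so image v grows toward the
#' posterior.
#'
#' @param height,forward camera position, mm.
#' @return list with `rotation` (world-to-camera) and `center` (world mm).
#' @export
defaultCameraPose <- function(height = 1500, forward = 100) {
  list(rotation = diag(c(1, -1, -1)), center = c(0, forward, height))
}
.defaultCameraPose <- defaultCameraPose

#' Render a depth map from a point set
#'
#' Z-buffer projection through the pinhole model: each point lands on the
#' pixel containing its projection and the pixel keeps the nearest (smallest
#' z) depth. Pixels receiving no projection are invalid.
#'
#' @param scene a [SyntheticScene-class] or an N x 3 point matrix (world mm).
#' @param camera a [CameraIntrinsics-class].
#' @param cameraPose list with `rotation` (world-to-camera) and `center`
#'   (optical centre, world mm); defaults to an overhead view 1500 mm up.
#' @param frameId,timestamp metadata for the resulting [DepthMap-class].
#' @return a [DepthMap-class] (values in mm, float precision).
#' @export
renderDepth <- function(scene, camera = defaultCamera(),
                        cameraPose = .defaultCameraPose(),
                        frameId = "synthetic", timestamp = "2021-04-15T10:00:00Z") {
  pts <- if (is(scene, "SyntheticScene")) scene@points else as.matrix(scene)
  stopifnot(ncol(pts) == 3)
  pc <- transformPoints(pts, cameraPose$rotation,
                        -as.numeric(cameraPose$rotation %*% cameraPose$center))
  z <- pc[, 3]
  keep <- z > 0
  if (!any(keep))
    bcsStop("emptyMap", "camera is behind the surface: no point projects with positive depth")
  u <- round(camera@fx * pc[keep, 1] / z[keep] + camera@cx)
  v <- round(camera@fy * pc[keep, 2] / z[keep] + camera@cy)
  zk <- z[keep]
  inb <- u >= 0 & u < camera@width & v >= 0 & v < camera@height
  if (!any(inb))
    bcsStop("emptyMap", "no point projects inside the image")
  u <- u[inb]; v <- v[inb]; zk <- zk[inb]
  ord <- order(zk, decreasing = TRUE)          # write far to near: near wins
  idx <- u[ord] * camera@height + v[ord] + 1   # column-major (row v+1, col u+1)
  vals <- matrix(0, camera@height, camera@width)
  vals[idx] <- zk[ord]
  DepthMap(values = vals, valid = vals > 0, intrinsics = camera,
           frameId = frameId, timestamp = timestamp)
}

#' Corrupt a depth map with sensor noise and dropout
#'
#' Adds i.i.d. Gaussian noise (sd `noiseSd` mm) to valid pixels and
#' invalidates an independent Bernoulli(`dropoutFrac`) subset. Deterministic
#' for a fixed seed.
#'
#' @param depth a [DepthMap-class].
#' @param noiseSd noise standard deviation, mm (>= 0).
#' @param dropoutFrac dropout probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a corrupted [DepthMap-class].
#' @export
corruptDepth <- function(depth, noiseSd = 3, dropoutFrac = 0.05, seed = 0L) {
  stopifnot(is(depth, "DepthMap"))
  if (noiseSd < 0) bcsStop("invalidArgument", "noiseSd must be >= 0")
  if (dropoutFrac < 0 || dropoutFrac >= 1)
    bcsStop("invalidArgument", "dropoutFrac must lie in [0, 1)")
  if (noiseSd == 0 && dropoutFrac == 0) return(depth)
  vals <- depth@values
  valid <- depth@valid
  nv <- sum(valid)
  withSeed(deriveSeed(seed, 1L), {
    if (noiseSd > 0)
      vals[valid] <- pmin(65535, pmax(.Machine$double.eps,
                                      vals[valid] + stats::rnorm(nv, 0, noiseSd)))
    if (dropoutFrac > 0) {
      drop <- stats::runif(nv) < dropoutFrac
      idx <- which(valid)[drop]
      valid[idx] <- FALSE
      vals[idx] <- 0
    }
  })
  DepthMap(values = vals, valid = valid, intrinsics = depth@intrinsics,
           frameId = depth@frameId, timestamp = depth@timestamp)
}

#' Simulate a cohort of synthetic heifers
#'
#' Draws per-animal true BCS uniformly on `bcsRange`, jitters morphology
#' around the packaged herd averages (hip width sd 25 mm, body length sd
#' 30 mm, withers height sd 47 mm), applies multiplicative log-normal
#' anatomic variation (sd `fatnessJitterSd` on the log scale) to each bony
#' prominence, poses each animal with a random yaw (<= 10 degrees), a small
#' tilt (<= 3 degrees) and a lateral/longitudinal offset (<= 40 mm), renders
#' an overhead depth frame and corrupts it with sensor noise and dropout.
#'
#' @param n number of animals.
#' @param bcsRange length-2 range for the uniform true BCS draw.
#' @param noiseSd,dropoutFrac sensor corruption, see [corruptDepth()].
#' @param seed integer run seed; animal i uses `deriveSeed(seed, i)`.
#' @param camera a [CameraIntrinsics-class].
#' @param fatnessJitterSd log-scale sd of the per-animal prominence jitter.
#' @return list with `scenes` (list of [SyntheticScene-class]), `depths`
#'   (list of corrupted [DepthMap-class]) and `truth` (data.frame with
#'   `animal_id`, `bcs_true` and landmark coordinates).
#' @export
simulateAnimals <- function(n, bcsRange = c(2.0, 3.5), noiseSd = 3,
                            dropoutFrac = 0.05, seed = 42L,
                            camera = defaultCamera(),
                            fatnessJitterSd = 0.08) {
  stopifnot(n >= 1, length(bcsRange) == 2, bcsRange[1] <= bcsRange[2])
  scenes <- vector("list", n)
  depths <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    si <- deriveSeed(seed, i)
    par <- withSeed(si, {
      list(bcs  = stats::runif(1, bcsRange[1], bcsRange[2]),
           hw   = min(580, max(440, stats::rnorm(1, 507, 25))),
           len  = min(540, max(360, stats::rnorm(1, 450, 30))),
           wh   = min(1520, max(1230, stats::rnorm(1, 1376, 47))),
           jit  = exp(stats::rnorm(4, 0, fatnessJitterSd)),
           yaw  = stats::runif(1, -10, 10) * pi / 180,
           tilt = stats::runif(1, -3, 3) * pi / 180,
           off  = stats::runif(2, -40, 40))
    })
    fp0 <- defaultFatness(par$bcs)
    fp <- FatnessParams(bcsTrue = par$bcs,
                        spineProminence     = fp0@spineProminence * par$jit[1],
                        hookProminence      = fp0@hookProminence * par$jit[2],
                        pinProminence       = fp0@pinProminence * par$jit[3],
                        tailDepressionDepth = fp0@tailDepressionDepth * par$jit[4])
    morph <- defaultMorphology(hip_width = par$hw, body_length = par$len,
                               withers_height = par$wh)
    pose <- list(rotation = rotZ(par$yaw) %*% rotX(par$tilt),
                 translation = c(par$off, 0))
    scene <- generateSurface(fp, morph, seed = si, pose = pose)
    depth <- renderDepth(scene, camera, frameId = sprintf("animal%03d", i))
    depth <- corruptDepth(depth, noiseSd, dropoutFrac, seed = deriveSeed(si, 2L))
    lm <- landmarkCoords(scene)
    scenes[[i]] <- scene
    depths[[i]] <- depth
    truth[[i]] <- data.frame(animal_id = sprintf("animal%03d", i),
                             bcs_true = par$bcs,
                             t(as.vector(t(lm))))
  }
  truth <- do.call(rbind, truth)
  names(truth)[-(1:2)] <- as.vector(t(outer(
    c("li", "ri", "ls", "rs"), c("x", "y", "z"), paste, sep = "_")))
  rownames(truth) <- NULL
  list(scenes = scenes, depths = depths, truth = truth)
}
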