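#' @import methods
NULL

#' Camera intrinsics for a pinhole depth sensor
#'
#' Pixel convention: (0, 0) is the centre of the top-left pixel, `u` grows
#' rightward, `v` downward, and the camera looks down its +z axis. `baseline`
#' is the separation of the stereo pair's optical centres in mm (0 for a mono
#' depth source).
#'
#' @slot fx,fy focal lengths in pixels.
#' @slot cx,cy principal point in pixels.
#' @slot width,height image size in pixels.
#' @slot baseline stereo baseline in mm.
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric", cy = "numeric",
                 width = "integer", height = "integer", baseline = "numeric"),
  validity = function(object) {
    if (object@fx <= 0 || object@fy <= 0) return("fx and fy must be > 0")
    if (object@cx < 0 || object@cx >= object@width) return("cx must lie in [0, width)")
    if (object@cy < 0 || object@cy >= object@height) return("cy must lie in [0, height)")
    if (object@baseline < 0) return("baseline must be >= 0")
    TRUE
  })

#' @param fx,fy,cx,cy,width,height,baseline see slots.
#' @rdname CameraIntrinsics-class
#' @export
CameraIntrinsics <- function(fx, fy, cx, cy, width, height, baseline = 0) {
  new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      width = as.integer(width), height = as.integer(height),
      baseline = as.numeric(baseline))
}

#' A single-view depth map
#'
#' Range along the optical axis in mm per pixel, with an explicit validity
#' mask. On disk the invalid sentinel is 0 mm (16-bit PNG); in memory the mask
#' is authoritative and values at invalid pixels are 0.
#'
#' @slot values height x width numeric matrix of depths (mm).
#' @slot valid logical matrix of the same shape.
#' @slot intrinsics a [CameraIntrinsics-class].
#' @slot frameId acquisition identifier.
#' @slot timestamp ISO-8601 date-time string.
#' @export
setClass("DepthMap",
  representation(values = "matrix", valid = "matrix",
                 intrinsics = "CameraIntrinsics",
                 frameId = "character", timestamp = "character"),
  validity = function(object) {
    if (!all(dim(object@values) == dim(object@valid)))
      return("values and valid must have identical dimensions")
    if (!is.logical(object@valid)) return("valid must be a logical matrix")
    v <- object@values[object@valid]
    if (length(v) && (any(!is.finite(v)) || any(v <= 0) || any(v > 65535)))
      return("valid depths must lie in (0, 65535] mm")
    TRUE
  })

#' @param values,valid,intrinsics,frameId,timestamp see slots.
#' @rdname DepthMap-class
#' @export
DepthMap <- function(values, valid = values > 0, intrinsics,
                     frameId = "frame", timestamp = "1970-01-01T00:00:00Z") {
  values[!valid] <- 0
  new("DepthMap", values = values, valid = valid, intrinsics = intrinsics,
      frameId = frameId, timestamp = timestamp)
}

#' A 3-D point cloud
#'
#' @slot points N x 3 numeric matrix of coordinates in mm.
#' @slot frame one of `"camera"`, `"world"`, `"canonical"`.
#' @export
setClass("PointCloud",
  representation(points = "matrix", frame = "character"),
  validity = function(object) {
    if (ncol(object@points) != 3) return("points must be N x 3")
    if (nrow(object@points) && any(!is.finite(object@points)))
      return("point coordinates must be finite")
    if (!object@frame %in% c("camera", "world", "canonical"))
      return("frame must be one of camera, world, canonical")
    TRUE
  })

#' @param points,frame see slots.
#' @rdname PointCloud-class
#' @export
PointCloud <- function(points, frame = "camera") {
  storage.mode(points) <- "double"
  new("PointCloud", points = points, frame = frame)
}

#' The four pelvic normalization landmarks
#'
#' Tops of the left/right ischia (pin bones) and bases of the left/right
#' sacra, with a detection confidence per landmark in `[0, 1]`.
#'
#' @slot coords 4 x 3 matrix with rows `left_ischium`, `right_ischium`,
#'   `left_sacrum`, `right_sacrum` (mm, in the frame of the source cloud).
#' @slot confidence numeric(4) in `[0, 1]`.
#' @export
setClass("LandmarkSet",
  representation(coords = "matrix", confidence = "numeric"),
  validity = function(object) {
    want <- c("left_ischium", "right_ischium", "left_sacrum", "right_sacrum")
    if (!all(dim(object@coords) == c(4, 3))) return("coords must be 4 x 3")
    if (!identical(rownames(object@coords), want))
      return("coords rows must be left_ischium, right_ischium, left_sacrum, right_sacrum")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    if (length(object@confidence) != 4 ||
        any(object@confidence < 0) || any(object@confidence > 1))
      return("confidence must be 4 values in [0, 1]")
    TRUE
  })

#' @param coords,confidence see slots.
#' @rdname LandmarkSet-class
#' @export
LandmarkSet <- function(coords, confidence = rep(1, 4)) {
  rownames(coords) <- c("left_ischium", "right_ischium", "left_sacrum", "right_sacrum")
  storage.mode(coords) <- "double"
  new("LandmarkSet", coords = coords, confidence = as.numeric(confidence))
}

#' The canonical animal frame
#'
#' A rigid map `p_canonical = rotation %*% p + translation` built from the four
#' landmarks: origin at their centroid, x from left to right ischium, y from
#' the ischium midpoint toward the sacrum midpoint (orthogonalized), z = x
#' cross y (dorsally, out of the back).
#'
#' @slot rotation 3 x 3 orthonormal matrix (rows are the canonical axes).
#' @slot translation numeric(3), mm.
#' @export
setClass("CanonicalFrame",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    if (!all(dim(object@rotation) == c(3, 3))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(object@rotation) - diag(3))) > 1e-8)
      return("rotation must be orthonormal")
    if (abs(det(object@rotation) - 1) > 1e-9)
      return("rotation determinant must be +1")
    if (length(object@translation) != 3) return("translation must be length 3")
    TRUE
  })

#' A dorsal surface resampled in the canonical frame
#'
#' Heights (mm, canonical z, so the landmark plane sits near zero) on a square
#' grid over the landmark-defined region of interest. The grid is
#' size-relative (fixed cell count over the ROI rectangle); the physical
#' extent is retained in `scaleRecord` rather than normalized away.
#'
#' @slot grid numeric matrix of heights (rows index canonical y from posterior
#'   to anterior, columns canonical x from left to right).
#' @slot valid logical matrix; FALSE where no cloud support existed.
#' @slot scaleRecord named numeric: physical ROI extent `width_mm`, `length_mm`.
#' @slot roi named numeric ROI rectangle `xmin`, `xmax`, `ymin`, `ymax` (mm).
#' @export
setClass("NormalizedSurface",
  representation(grid = "matrix", valid = "matrix",
                 scaleRecord = "numeric", roi = "numeric"),
  validity = function(object) {
    if (!all(dim(object@grid) == dim(object@valid)))
      return("grid and valid must have identical dimensions")
    if (nrow(object@grid) != ncol(object@grid)) return("grid must be square")
    if (any(!is.finite(object@grid[object@valid])))
      return("heights must be finite where valid")
    TRUE
  })

NormalizedSurface <- function(grid, valid, scaleRecord, roi) {
  new("NormalizedSurface", grid = grid, valid = valid,
      scaleRecord = scaleRecord, roi = roi)
}

#' Latent fatness geometry of a synthetic heifer
#'
#' Houses the latent trait that body condition scoring reads off the dorsal
#' surface: bony prominences (mm) that shrink as the animal fattens. Under the
#' default mapping ([defaultFatness()]) every prominence is a strictly
#' decreasing affine function of the true BCS, reaching 0 at BCS 5.
#'
#' @slot bcsTrue true body condition score on the 0-5 scale.
#' @slot spineProminence height of the vertebral ridge above paravertebral
#'   tissue, mm.
#' @slot hookProminence protrusion of the hip (hook) bones, mm; also scales
#'   the sacral prominences.
#' @slot pinProminence protrusion of the ischia (pin bones), mm.
#' @slot tailDepressionDepth depth of the tail-head depression, mm.
#' @export
setClass("FatnessParams",
  representation(bcsTrue = "numeric", spineProminence = "numeric",
                 hookProminence = "numeric", pinProminence = "numeric",
                 tailDepressionDepth = "numeric"),
  validity = function(object) {
    if (object@bcsTrue < 0 || object@bcsTrue > 5) return("bcsTrue must lie in [0, 5]")
    p <- c(object@spineProminence, object@hookProminence,
           object@pinProminence, object@tailDepressionDepth)
    if (any(p < 0)) return("prominence values must be >= 0")
    TRUE
  })

#' @param bcsTrue,spineProminence,hookProminence,pinProminence,tailDepressionDepth
#'   see slots.
#' @rdname FatnessParams-class
#' @export
FatnessParams <- function(bcsTrue, spineProminence, hookProminence,
                          pinProminence, tailDepressionDepth) {
  new("FatnessParams", bcsTrue = bcsTrue, spineProminence = spineProminence,
      hookProminence = hookProminence, pinProminence = pinProminence,
      tailDepressionDepth = tailDepressionDepth)
}

#' A synthetic dorsal scene
#'
#' A densely sampled parametric hips-to-pins surface, its four ground-truth
#' landmarks (exact mesh vertices), the generating fatness parameters, the
#' applied body pose and the body dimensions used.
#'
#' @slot points N x 3 point set, mm, world frame (pose applied).
#' @slot landmarks ground-truth [LandmarkSet-class] (pose applied).
#' @slot fatness [FatnessParams-class].
#' @slot pose list with `rotation` (3 x 3) and `translation` (numeric(3)).
#' @slot morphology named list: `hip_width`, `body_length`, `withers_height` (mm).
#' @export
setClass("SyntheticScene",
  representation(points = "matrix", landmarks = "LandmarkSet",
                 fatness = "FatnessParams", pose = "list", morphology = "list"))

#' PCA-regression shape model for BCS prediction
#'
#' Mean surface plus an orthonormal PCA basis over flattened normalized
#' surfaces, and ordinary-least-squares coefficients regressing BCS on the
#' PCA coordinates.
#'
#' @slot meanSurface numeric(p), flattened mean surface (column-major).
#' @slot components k x p row-orthonormal basis.
#' @slot explainedVariance numeric(k), fraction of variance per component.
#' @slot coefficients numeric(k + 1), intercept first.
#' @slot k retained component count.
#' @slot gridDim integer(2), grid dimensions of the training surfaces.
#' @slot trainingMeta list: `n_train`, `seed`, `variance_threshold`, `k_max`.
#' @export
setClass("ShapeModel",
  representation(meanSurface = "numeric", components = "matrix",
                 explainedVariance = "numeric", coefficients = "numeric",
                 k = "integer", gridDim = "integer", trainingMeta = "list"),
  validity = function(object) {
    k <- object@k
    if (nrow(object@components) != k) return("components must have k rows")
    if (k > 0) {
      g <- tcrossprod(object@components)
      if (max(abs(g - diag(k))) > 1e-8) return("components must be row-orthonormal")
    }
    ev <- object@explainedVariance
    if (length(ev) != k) return("explainedVariance must have length k")
    if (k > 1 && any(diff(ev) > 1e-12)) return("explainedVariance must be non-increasing")
    if (sum(ev) > 1 + 1e-9) return("explainedVariance must sum to <= 1")
    cf <- object@coefficients
    unfitted <- length(cf) == 1 && is.na(cf)  # PCA-only model
    if (!unfitted && length(cf) != k + 1)
      return("coefficients must have length k + 1 (intercept first)")
    TRUE
  })

#' Acquisition quality of one depth frame
#'
#' A documented surrogate for the device's 1-4 quality rubric, with the "+"
#' suffix (entire animal including the head) carried as `fullBody`.
#'
#' @slot grade integer in 1..4.
#' @slot fullBody logical, TRUE when valid pixels cover the head zone.
#' @slot validFraction fraction of the expected body region with valid depth.
#' @slot roiValidFraction fraction of the hips-to-pins core region with valid depth.
#' @export
setClass("QualityScore",
  representation(grade = "integer", fullBody = "logical",
                 validFraction = "numeric", roiValidFraction = "numeric"),
  validity = function(object) {
    if (object@grade < 1L || object@grade > 4L) return("grade must be in 1..4")
    TRUE
  })

#' A LOESS-smoothed longitudinal curve
#'
#' @slot x numeric abscissae (days from the first record).
#' @slot fitted fitted values at `x`.
#' @slot span neighbourhood fraction used.
#' @slot degree local polynomial degree (1 or 2).
#' @export
setClass("SmoothCurve",
  representation(x = "numeric", fitted = "numeric",
                 span = "numeric", degree = "integer"),
  validity = function(object) {
    if (length(object@x) != length(object@fitted))
      return("x and fitted must have equal length")
    if (!object@degree %in% c(1L, 2L)) return("degree must be 1 or 2")
    if (object@span <= 0 || object@span > 1) return("span must lie in (0, 1]")
    TRUE
  })
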