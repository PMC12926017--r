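#' Accessors for bcs3d classes
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param object a bcs3d S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("depthValues", function(object) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setMethod("depthValues", "DepthMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "DepthMap", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "NormalizedSurface", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("intrinsics", function(object) standardGeneric("intrinsics"))
#' @rdname accessors
#' @export
setMethod("intrinsics", "DepthMap", function(object) object@intrinsics)

#' @rdname accessors
#' @export
setGeneric("frameId", function(object) standardGeneric("frameId"))
#' @rdname accessors
#' @export
setMethod("frameId", "DepthMap", function(object) object@frameId)

#' @rdname accessors
#' @export
setGeneric("timestamp", function(object) standardGeneric("timestamp"))
#' @rdname accessors
#' @export
setMethod("timestamp", "DepthMap", function(object) object@timestamp)

#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setMethod("cloudPoints", "PointCloud", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("cloudPoints", "SyntheticScene", function(object) object@points)

#' @rdname accessors
#' @export
setGeneric("cloudFrame", function(object) standardGeneric("cloudFrame"))
#' @rdname accessors
#' @export
setMethod("cloudFrame", "PointCloud", function(object) object@frame)

#' @rdname accessors
#' @export
setGeneric("landmarkCoords", function(object) standardGeneric("landmarkCoords"))
#' @rdname accessors
#' @export
setMethod("landmarkCoords", "LandmarkSet", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("landmarkCoords", "SyntheticScene", function(object) object@landmarks@coords)

#' @rdname accessors
#' @export
setGeneric("landmarkConfidence", function(object) standardGeneric("landmarkConfidence"))
#' @rdname accessors
#' @export
setMethod("landmarkConfidence", "LandmarkSet", function(object) object@confidence)

#' @rdname accessors
#' @export
setGeneric("trueLandmarks", function(object) standardGeneric("trueLandmarks"))
#' @rdname accessors
#' @export
setMethod("trueLandmarks", "SyntheticScene", function(object) object@landmarks)

#' @rdname accessors
#' @export
setGeneric("fatness", function(object) standardGeneric("fatness"))
#' @rdname accessors
#' @export
setMethod("fatness", "SyntheticScene", function(object) object@fatness)

#' @rdname accessors
#' @export
setGeneric("morphology", function(object) standardGeneric("morphology"))
#' @rdname accessors
#' @export
setMethod("morphology", "SyntheticScene", function(object) object@morphology)

#' @rdname accessors
#' @export
setGeneric("bodyPose", function(object) standardGeneric("bodyPose"))
#' @rdname accessors
#' @export
setMethod("bodyPose", "SyntheticScene", function(object) object@pose)

#' @rdname accessors
#' @export
setGeneric("bcsTrue", function(object) standardGeneric("bcsTrue"))
#' @rdname accessors
#' @export
setMethod("bcsTrue", "FatnessParams", function(object) object@bcsTrue)
#' @rdname accessors
#' @export
setMethod("bcsTrue", "SyntheticScene", function(object) object@fatness@bcsTrue)

#' @rdname accessors
#' @export
setGeneric("prominences", function(object) standardGeneric("prominences"))
#' @rdname accessors
#' @export
setMethod("prominences", "FatnessParams", function(object)
  c(spine = object@spineProminence, hook = object@hookProminence,
    pin = object@pinProminence, tail_depression = object@tailDepressionDepth))

#' @rdname accessors
#' @export
setGeneric("surfaceGrid", function(object) standardGeneric("surfaceGrid"))
#' @rdname accessors
#' @export
setMethod("surfaceGrid", "NormalizedSurface", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("scaleRecord", function(object) standardGeneric("scaleRecord"))
#' @rdname accessors
#' @export
setMethod("scaleRecord", "NormalizedSurface", function(object) object@scaleRecord)

#' @rdname accessors
#' @export
setGeneric("validFraction", function(object) standardGeneric("validFraction"))
#' @rdname accessors
#' @export
setMethod("validFraction", "NormalizedSurface", function(object) mean(object@valid))
#' @rdname accessors
#' @export
setMethod("validFraction", "QualityScore", function(object) object@validFraction)

#' @rdname accessors
#' @export
setGeneric("frameRotation", function(object) standardGeneric("frameRotation"))
#' @rdname accessors
#' @export
setMethod("frameRotation", "CanonicalFrame", function(object) object@rotation)

#' @rdname accessors
#' @export
setGeneric("frameTranslation", function(object) standardGeneric("frameTranslation"))
#' @rdname accessors
#' @export
setMethod("frameTranslation", "CanonicalFrame", function(object) object@translation)

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "ShapeModel", function(object) object@k)

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setMethod("explainedVariance", "ShapeModel", function(object) object@explainedVariance)

#' @rdname accessors
#' @export
setGeneric("meanSurface", function(object) standardGeneric("meanSurface"))
#' @rdname accessors
#' @export
setMethod("meanSurface", "ShapeModel", function(object) object@meanSurface)

#' @rdname accessors
#' @export
setGeneric("shapeComponents", function(object) standardGeneric("shapeComponents"))
#' @rdname accessors
#' @export
setMethod("shapeComponents", "ShapeModel", function(object) object@components)

#' @rdname accessors
#' @export
setMethod("coef", "ShapeModel", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setGeneric("trainingMeta", function(object) standardGeneric("trainingMeta"))
#' @rdname accessors
#' @export
setMethod("trainingMeta", "ShapeModel", function(object) object@trainingMeta)

#' @rdname accessors
#' @export
setGeneric("qualityGrade", function(object) standardGeneric("qualityGrade"))
#' @rdname accessors
#' @export
setMethod("qualityGrade", "QualityScore", function(object) object@grade)

#' @rdname accessors
#' @export
setGeneric("fullBody", function(object) standardGeneric("fullBody"))
#' @rdname accessors
#' @export
setMethod("fullBody", "QualityScore", function(object) object@fullBody)

#' @rdname accessors
#' @export
setGeneric("roiValidFraction", function(object) standardGeneric("roiValidFraction"))
#' @rdname accessors
#' @export
setMethod("roiValidFraction", "QualityScore", function(object) object@roiValidFraction)

#' @rdname accessors
#' @export
setGeneric("curveFitted", function(object) standardGeneric("curveFitted"))
#' @rdname accessors
#' @export
setMethod("curveFitted", "SmoothCurve", function(object) object@fitted)

#' @rdname accessors
#' @export
setGeneric("curveX", function(object) standardGeneric("curveX"))
#' @rdname accessors
#' @export
setMethod("curveX", "SmoothCurve", function(object) object@x)

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %dx%d px, fx=%.1f fy=%.1f cx=%.1f cy=%.1f, baseline=%.1f mm\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy, object@baseline))
})

setMethod("show", "DepthMap", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("DepthMap %dx%d px, %.1f%% valid%s [%s]\n",
              nrow(object@values), ncol(object@values), 100 * mean(object@valid),
              if (length(v)) sprintf(", range %.0f-%.0f mm", min(v), max(v)) else "",
              object@frameId))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points (%s frame)\n",
              nrow(object@points), object@frame))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet (mm):\n")
  m <- cbind(round(object@coords, 1), confidence = round(object@confidence, 2))
  print(m)
})

setMethod("show", "NormalizedSurface", function(object) {
  cat(sprintf("NormalizedSurface %dx%d, %.1f%% valid, ROI %.0f x %.0f mm\n",
              nrow(object@grid), ncol(object@grid), 100 * mean(object@valid),
              object@scaleRecord[["width_mm"]], object@scaleRecord[["length_mm"]]))
})

setMethod("show", "FatnessParams", function(object) {
  cat(sprintf("FatnessParams: BCS %.2f | spine %.1f, hook %.1f, pin %.1f, tail %.1f mm\n",
              object@bcsTrue, object@spineProminence, object@hookProminence,
              object@pinProminence, object@tailDepressionDepth))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d points, BCS %.2f, hip width %.0f mm\n",
              nrow(object@points), object@fatness@bcsTrue,
              object@morphology$hip_width))
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel: k=%d components (%.1f%% variance), trained on n=%s\n",
              object@k, 100 * sum(object@explainedVariance),
              object@trainingMeta$n_train %||% "?"))
})

setMethod("show", "QualityScore", function(object) {
  cat(sprintf("QualityScore: grade %d%s (body %.0f%%, ROI %.0f%% valid)\n",
              object@grade, if (object@fullBody) "+" else "",
              100 * object@validFraction, 100 * object@roiValidFraction))
})

setMethod("show", "SmoothCurve", function(object) {
  cat(sprintf("SmoothCurve: %d points, span %.2f, degree %d\n",
              length(object@x), object@span, object@degree))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
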