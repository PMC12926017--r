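## Landmark-based normalization: canonical animal frame and resampling of the
## hips-to-pins region of interest onto a fixed square grid.

#' Build the canonical animal frame from the four landmarks
#'
#' Origin at the landmark centroid; x is the unit vector from the left to the
#' right ischium; y points from the ischium midpoint toward the sacrum
#' midpoint, orthogonalized against x; z = x cross y (dorsal). The returned
#' frame maps cloud coordinates into this canonical pose,
#' `p' = R p + t`.
#'
#' @param lm a [LandmarkSet-class].
#' @return a [CanonicalFrame-class].
#' @export
computeFrame <- function(lm) {
  stopifnot(is(lm, "LandmarkSet"))
  co <- lm@coords
  ctr <- colMeans(co)
  xv <- co["right_ischium", ] - co["left_ischium", ]
  nx <- sqrt(sum(xv^2))
  yraw <- (co["left_sacrum", ] + co["right_sacrum", ]) / 2 -
    (co["left_ischium", ] + co["right_ischium", ]) / 2
  if (nx < 1e-9)
    bcsStop("degenerateGeometry", "ischium landmarks are coincident")
  xh <- xv / nx
  yv <- yraw - sum(yraw * xh) * xh
  ny <- sqrt(sum(yv^2))
  if (ny < 1e-9)
    bcsStop("degenerateGeometry", "landmarks are collinear")
  yh <- yv / ny
  zh <- c(xh[2] * yh[3] - xh[3] * yh[2],
          xh[3] * yh[1] - xh[1] * yh[3],
          xh[1] * yh[2] - xh[2] * yh[1])
  R <- rbind(xh, yh, zh)
  dimnames(R) <- NULL
  new("CanonicalFrame", rotation = R, translation = as.numeric(-R %*% ctr))
}

#' Apply a canonical frame to points
#'
#' @param frame a [CanonicalFrame-class].
#' @param points N x 3 matrix, or a [PointCloud-class].
#' @return transformed N x 3 matrix (or canonical-frame [PointCloud-class]).
#' @export
applyFrame <- function(frame, points) {
  stopifnot(is(frame, "CanonicalFrame"))
  if (is(points, "PointCloud"))
    return(PointCloud(transformPoints(points@points, frame@rotation,
                                      frame@translation), frame = "canonical"))
  transformPoints(points, frame@rotation, frame@translation)
}

#' Resample the hips-to-pins region onto a fixed grid
#'
#' The ROI rectangle is the bounding box of the four canonical-frame
#' landmarks, expanded by `margin` (fraction of each extent) on every side.
#' Heights (canonical z) are interpolated at the `gridN` x `gridN` cell
#' centres by inverse-distance weighting of the `k` nearest in-ROI points
#' within radius `radius` mm; cells with no neighbour inside the radius are
#' invalid. The grid is size-relative; the physical extent is retained in the
#' result's `scaleRecord`.
#'
#' @param cloud a [PointCloud-class] (any frame; transformed internally).
#' @param frame the [CanonicalFrame-class] from [roiFrame()] (or
#'   [computeFrame()] together with `lm`).
#' @param gridN grid cell count per side (150 by convention).
#' @param margin ROI expansion fraction per side.
#' @param k,radius interpolation neighbourhood (points, mm).
#' @param minPoints minimum number of in-ROI points.
#' @param lm optionally the [LandmarkSet-class] defining the ROI box, when
#'   `frame` was built with [computeFrame()] directly.
#' @return a [NormalizedSurface-class].
#' @export
extractROI <- function(cloud, frame, gridN = 150L, margin = 0.1,
                       k = 8L, radius = 25, minPoints = 1000L, lm = NULL) {
  stopifnot(is(cloud, "PointCloud"), is(frame, "CanonicalFrame"))
  pc <- transformPoints(cloud@points, frame@rotation, frame@translation)
  box <- attr(frame, "roiBox")
  if (is.null(box) && !is.null(lm)) {
    lc <- transformPoints(lm@coords, frame@rotation, frame@translation)
    box <- c(xmin = min(lc[, 1]), xmax = max(lc[, 1]),
             ymin = min(lc[, 2]), ymax = max(lc[, 2]))
  }
  if (is.null(box))
    bcsStop("invalidArgument",
            "frame carries no ROI box; build it with roiFrame() or pass lm")
  ex <- box["xmax"] - box["xmin"]; ey <- box["ymax"] - box["ymin"]
  roi <- c(xmin = unname(box["xmin"] - margin * ex),
           xmax = unname(box["xmax"] + margin * ex),
           ymin = unname(box["ymin"] - margin * ey),
           ymax = unname(box["ymax"] + margin * ey))
  inroi <- pc[, 1] >= roi["xmin"] & pc[, 1] <= roi["xmax"] &
    pc[, 2] >= roi["ymin"] & pc[, 2] <= roi["ymax"]
  if (sum(inroi) < minPoints)
    bcsStop("degenerateInput",
            sprintf("only %d points fall in the ROI; need %d", sum(inroi), minPoints))
  px <- pc[inroi, 1]; py <- pc[inroi, 2]; pz <- pc[inroi, 3]
  dx <- (roi["xmax"] - roi["xmin"]) / gridN
  dy <- (roi["ymax"] - roi["ymin"]) / gridN
  res <- .idwResampleCpp(px, py, pz,
                         roi[["xmin"]], dx, as.integer(gridN),
                         roi[["ymin"]], dy, as.integer(gridN),
                         as.integer(k), radius)
  vals <- res$values
  vals[!res$valid] <- NA_real_
  NormalizedSurface(grid = vals, valid = res$valid,
                    scaleRecord = c(width_mm = unname(roi["xmax"] - roi["xmin"]),
                                    length_mm = unname(roi["ymax"] - roi["ymin"])),
                    roi = roi)
}

#' Canonical frame carrying its landmark ROI box
#'
#' Convenience wrapper: computes the frame from the landmarks and attaches
#' the canonical-frame bounding box of the landmarks, which [extractROI()]
#' expands into the sampling rectangle.
#'
#' @param lm a [LandmarkSet-class].
#' @return a [CanonicalFrame-class] with an ROI box attribute.
#' @export
roiFrame <- function(lm) {
  fr <- computeFrame(lm)
  lc <- transformPoints(lm@coords, fr@rotation, fr@translation)
  attr(fr, "roiBox") <- c(xmin = min(lc[, 1]), xmax = max(lc[, 1]),
                          ymin = min(lc[, 2]), ymax = max(lc[, 2]))
  fr
}

#' Fill invalid grid cells by iterative neighbour averaging
#'
#' Invalid cells are initialized at the mean valid height and relaxed by
#' Jacobi iteration of the 4-neighbour average (a discrete harmonic fill)
#' until the largest update is below `tol` mm. The original validity mask is
#' preserved for audit. Surfaces with a valid fraction below `minValid` are
#' rejected.
#'
#' @param surface a [NormalizedSurface-class].
#' @param minValid minimum acceptable valid fraction.
#' @param tol convergence tolerance, mm.
#' @param maxIter iteration cap.
#' @return a [NormalizedSurface-class] with a complete grid.
#' @export
imputeSurface <- function(surface, minValid = 0.6, tol = 1e-6, maxIter = 10000L) {
  stopifnot(is(surface, "NormalizedSurface"))
  vf <- mean(surface@valid)
  if (vf < minValid)
    bcsStop("qualityReject",
            sprintf("valid fraction %.2f below floor %.2f", vf, minValid))
  G <- surface@grid
  V <- surface@valid
  if (all(V)) return(surface)
  G[!V] <- mean(G[V])
  n <- nrow(G); m <- ncol(G)
  up <- function(M) rbind(M[1, , drop = FALSE], M[-n, , drop = FALSE])
  dn <- function(M) rbind(M[-1, , drop = FALSE], M[n, , drop = FALSE])
  lf <- function(M) cbind(M[, 1, drop = FALSE], M[, -m, drop = FALSE])
  rt <- function(M) cbind(M[, -1, drop = FALSE], M[, m, drop = FALSE])
  for (it in seq_len(maxIter)) {
    avg <- (up(G) + dn(G) + lf(G) + rt(G)) / 4
    delta <- avg - G
    delta[V] <- 0
    G <- G + delta
    if (max(abs(delta)) < tol) break
  }
  NormalizedSurface(grid = G, valid = V, scaleRecord = surface@scaleRecord,
                    roi = surface@roi)
}
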