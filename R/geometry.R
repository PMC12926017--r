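## Camera geometry: stereo correspondence, triangulation, and conversions
## between depth maps and point clouds.

# summed-area box filter (window w odd) of a matrix, interior cells only;
# border cells are NA
.boxSum <- function(m, w) {
  h <- w %/% 2
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  pad[-1, -1] <- cs
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  r <- (h + 1):(nr - h); c <- (h + 1):(nc - h)
  out[r, c] <- pad[r + h + 1, c + h + 1] - pad[r - h, c + h + 1] -
    pad[r + h + 1, c - h] + pad[r - h, c - h]
  out
}

#' Dense integer disparity by block matching
#'
#' For each pixel of the rectified left image, finds the integer disparity
#' `d` in `0..maxDisp` minimizing the sum of absolute differences over a
#' square window against the right image shifted along the same row. Ties are
#' broken toward the smaller disparity. Pixels whose window leaves either
#' image are invalid (`NA`).
#'
#' @param left,right numeric matrices of equal size (rectified pair).
#' @param window odd window size >= 3.
#' @param maxDisp maximum disparity searched, >= 1.
#' @return matrix of integer disparities, `NA` where no admissible match.
#' @export
findDisparity <- function(left, right, window = 9L, maxDisp = 64L) {
  if (!all(dim(left) == dim(right)))
    bcsStop("invalidArgument", "left and right images must have identical dimensions")
  if (window < 3 || window %% 2 == 0)
    bcsStop("invalidArgument", "window must be odd and >= 3")
  if (maxDisp < 1) bcsStop("invalidArgument", "maxDisp must be >= 1")
  nr <- nrow(left); nc <- ncol(left)
  h <- window %/% 2
  best <- matrix(Inf, nr, nc)
  disp <- matrix(NA_real_, nr, nc)
  for (d in 0:maxDisp) {
    if (nc - d < window) break
    cost <- matrix(Inf, nr, nc)
    ad <- abs(left[, (d + 1):nc, drop = FALSE] - right[, 1:(nc - d), drop = FALSE])
    bs <- .boxSum(ad, window)
    cost[, (d + 1):nc] <- bs
    upd <- which(is.finite(cost) & cost < best)
    best[upd] <- cost[upd]
    disp[upd] <- d
  }
  disp
}

#' Triangulate depth from disparity
#'
#' `z = fx * baseline / disparity` for strictly positive disparities;
#' disparity 0 or `NA` yields an invalid pixel (no division is attempted).
#'
#' @param disp disparity matrix in pixels.
#' @param cam a [CameraIntrinsics-class] with `baseline > 0`.
#' @return a [DepthMap-class].
#' @export
disparityToDepth <- function(disp, cam) {
  stopifnot(is(cam, "CameraIntrinsics"))
  if (cam@baseline <= 0)
    bcsStop("invalidArgument", "baseline must be > 0 to triangulate")
  valid <- is.finite(disp) & disp > 0
  z <- matrix(0, nrow(disp), ncol(disp))
  z[valid] <- cam@fx * cam@baseline / disp[valid]
  ok <- valid & z <= 65535
  z[!ok] <- 0
  DepthMap(values = z, valid = ok, intrinsics = cam, frameId = "triangulated")
}

#' Back-project a depth map to a camera-frame point cloud
#'
#' For each valid pixel `(u, v)` with depth `z`:
#' `x = (u - cx) z / fx`, `y = (v - cy) z / fy`. The number of points equals
#' the number of valid pixels.
#'
#' @param depth a [DepthMap-class].
#' @return a [PointCloud-class] in the camera frame.
#' @export
depthToPointCloud <- function(depth) {
  stopifnot(is(depth, "DepthMap"))
  cam <- depth@intrinsics
  idx <- which(depth@valid)
  if (!length(idx))
    return(PointCloud(matrix(numeric(0), 0, 3), frame = "camera"))
  h <- nrow(depth@values)
  v <- (idx - 1) %% h          # 0-based pixel row
  u <- (idx - 1) %/% h         # 0-based pixel column
  z <- depth@values[idx]
  PointCloud(cbind((u - cam@cx) * z / cam@fx,
                   (v - cam@cy) * z / cam@fy,
                   z), frame = "camera")
}

#' Project camera-frame points to pixel coordinates
#'
#' The exact inverse of [depthToPointCloud()] at float precision:
#' `u = fx x / z + cx`, `v = fy y / z + cy`.
#'
#' @param points N x 3 camera-frame points with z > 0.
#' @param cam a [CameraIntrinsics-class].
#' @return N x 2 matrix of (u, v) pixel coordinates (not rounded).
#' @export
projectPoints <- function(points, cam) {
  stopifnot(is.matrix(points), ncol(points) == 3, all(points[, 3] > 0))
  cbind(u = cam@fx * points[, 1] / points[, 3] + cam@cx,
        v = cam@fy * points[, 2] / points[, 3] + cam@cy)
}

#' Transform a camera-frame cloud into the world frame
#'
#' Inverts the world-to-camera pose used at rendering:
#' `p_world = R^T p_camera + center`.
#'
#' @param cloud a [PointCloud-class] in the camera frame.
#' @param cameraPose list with `rotation` (world-to-camera) and `center`.
#' @return a [PointCloud-class] in the world frame.
#' @export
cameraToWorld <- function(cloud, cameraPose) {
  stopifnot(is(cloud, "PointCloud"), cloudFrame(cloud) == "camera")
  PointCloud(transformPoints(cloud@points, t(cameraPose$rotation),
                             cameraPose$center), frame = "world")
}
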