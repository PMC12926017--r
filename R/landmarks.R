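## Automatic detection of the four pelvic landmarks on a dorsal point cloud.
##
## Pipeline (deterministic, no learned parts):
##   (a) sagittal plane by robust symmetry fit: grid search over plane
##       orientations through the cloud centroid, minimizing the left/right
##       reflection residual of a coarse height raster;
##   (b) ischia: per lateral half, the most posterior local height maximum of
##       the detrended raster exceeding a prominence threshold;
##   (c) sacrum bases: per half, the height-profile inflection (zero crossing
##       of the second difference along the body axis) adjacent to the
##       tail-head depression, below the sacral prominence peak.
## Landmark confidences are the feature prominences relative to the threshold.
## Operating envelope: roughly overhead view, body yaw within ~15 degrees of
## the rig axis.

#' Detection parameters for [detectLandmarks()]
#'
#' @param prominenceThresh minimum feature prominence, mm (default 3, about
#'   one sensor noise sd). Below it a landmark is still localized but reported
#'   with confidence 0 (detection-failure result).
#' @param cell raster cell size, mm.
#' @param midHalfWidth half width of the midline band used for the tail-head
#'   depression profile, mm.
#' @param hipWidthPrior expected ischium separation, mm; bounds the lateral
#'   search bands and the plausibility check (separation < 1.5 x prior).
#' @param searchAngleDeg half range of the sagittal-plane orientation search,
#'   degrees about the rig axis.
#' @param sacrumBandMax anterior extent (mm past the tail depression) searched
#'   for the sacral prominences.
#' @param minPoints minimum cloud size; fewer points is a degenerate input.
#' @return a named list of parameters.
#' @export
landmarkConfig <- function(prominenceThresh = 3, cell = 8, midHalfWidth = 40,
                           hipWidthPrior = 507, searchAngleDeg = 25,
                           sacrumBandMax = 170, minPoints = 1000) {
  list(prominenceThresh = prominenceThresh, cell = cell,
       midHalfWidth = midHalfWidth, hipWidthPrior = hipWidthPrior,
       searchAngleDeg = searchAngleDeg, sacrumBandMax = sacrumBandMax,
       minPoints = minPoints)
}

# mean-height raster anchored at the (equivariant) centroid in both axes;
# rows index v, columns u
.binGrid <- function(u, v, h, cell) {
  nuh <- ceiling(max(abs(u)) / cell + 1e-9)
  nu <- 2L * nuh
  iu <- pmin(nu, pmax(1L, floor(u / cell) + nuh + 1L))
  nvh <- ceiling(max(abs(v)) / cell + 1e-9)
  nv <- 2L * nvh
  iv <- pmin(nv, pmax(1L, floor(v / cell) + nvh + 1L))
  v0 <- -nvh * cell
  idx <- (iu - 1L) * nv + iv
  nb <- nv * nu
  counts <- tabulate(idx, nb)
  sums <- numeric(nb)
  rs <- rowsum(h, idx)
  sums[as.integer(rownames(rs))] <- rs
  H <- matrix(sums / pmax(counts, 1L), nv, nu)
  H[counts == 0] <- NA_real_
  list(H = H, counts = matrix(counts, nv, nu),
       uc = (seq_len(nu) - nuh - 0.5) * cell,
       vc = v0 + (seq_len(nv) - 0.5) * cell)
}

# 3x3 NA-aware mean filter
.smoothNA <- function(H) {
  nv <- nrow(H); nu <- ncol(H)
  S <- matrix(0, nv, nu); C <- matrix(0, nv, nu)
  for (dv in -1:1) for (du in -1:1) {
    rs <- max(1, 1 + dv):min(nv, nv + dv)
    rd <- max(1, 1 - dv):min(nv, nv - dv)
    cs <- max(1, 1 + du):min(nu, nu + du)
    cd <- max(1, 1 - du):min(nu, nu - du)
    blk <- H[rs, cs, drop = FALSE]
    ok <- !is.na(blk)
    blk[!ok] <- 0
    S[rd, cd] <- S[rd, cd] + blk
    C[rd, cd] <- C[rd, cd] + ok
  }
  out <- S / pmax(C, 1)
  out[C == 0] <- NA_real_
  out
}

# reflection residual of a coarse raster for one candidate sagittal angle
.symmetryResidual <- function(dx, dy, h, theta, cell = 16) {
  ct <- cos(theta); st <- sin(theta)
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  g <- .binGrid(u, v, h, cell)
  M <- g$H
  Mm <- M[, rev(seq_len(ncol(M))), drop = FALSE]
  both <- !is.na(M) & !is.na(Mm)
  either <- !is.na(M) | !is.na(Mm)
  if (sum(both) < 0.3 * sum(either) || sum(both) < 20) return(Inf)
  mean(abs(M[both] - Mm[both]))
}

# 1-D parabolic sub-cell peak offset from three samples, in cell units
.parabolicOffset <- function(ym, y0, yp) {
  if (any(!is.finite(c(ym, y0, yp)))) return(0)
  den <- ym - 2 * y0 + yp
  if (abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

# mean raw height of cloud points within `radius` of planar position (u0, v0)
.localHeight <- function(u, v, h, u0, v0, radius = 6, fallback = NA_real_) {
  sel <- abs(u - u0) <= radius & abs(v - v0) <= radius
  if (sum(sel) >= 3) {
    d2 <- (u[sel] - u0)^2 + (v[sel] - v0)^2
    keep <- d2 <= radius^2
    if (sum(keep) >= 3) return(mean(h[sel][keep]))
  }
  fallback
}

# quadratic detrend of raster cells; returns residuals at the given cells
.detrendQuad <- function(uu, vv, z) {
  X <- cbind(1, uu, vv, uu^2, vv^2, uu * vv)
  fit <- stats::lm.fit(X, z)
  fit$residuals
}

#' Detect the four pelvic landmarks
#'
#' See the module description above for the algorithm. When no feature
#' prominence exceeds the threshold the best-guess location is still
#' returned, flagged with confidence 0 rather than raising an error.
#'
#' @param cloud a [PointCloud-class] covering the rear-dorsal region
#'   (camera or world frame; camera-frame clouds are interpreted as viewed
#'   from above, i.e. height = -z).
#' @param config a [landmarkConfig()] list.
#' @return a [LandmarkSet-class] in the frame of `cloud`.
#' @export
detectLandmarks <- function(cloud, config = landmarkConfig()) {
  stopifnot(is(cloud, "PointCloud"))
  pts <- cloud@points
  if (nrow(pts) < config$minPoints)
    bcsStop("degenerateInput",
            sprintf("cloud has %d points; need at least %d", nrow(pts), config$minPoints))
  flip <- cloudFrame(cloud) == "camera"
  P <- if (flip) cbind(pts[, 1], -pts[, 2], -pts[, 3]) else pts
  cen <- colMeans(P)
  dx <- P[, 1] - cen[1]; dy <- P[, 2] - cen[2]; h <- P[, 3]

  # (a) sagittal plane orientation by symmetry grid search + refinement
  n <- length(dx)
  sub <- if (n > 4000) round(seq(1, n, length.out = 4000)) else seq_len(n)
  dxs <- dx[sub]; dys <- dy[sub]; hs <- h[sub]
  resFun <- function(th) .symmetryResidual(dxs, dys, hs, th)
  amax <- config$searchAngleDeg * pi / 180
  coarse <- seq(-amax, amax, by = 2.5 * pi / 180)
  rc <- vapply(coarse, resFun, numeric(1))
  th0 <- coarse[which.min(rc)]
  fine <- seq(th0 - 2 * pi / 180, th0 + 2 * pi / 180, by = 0.4 * pi / 180)
  rf <- vapply(fine, resFun, numeric(1))
  ib <- which.min(rf)
  theta <- fine[ib]
  if (ib > 1 && ib < length(fine) && all(is.finite(rf[ib + c(-1, 0, 1)])))
    theta <- theta +
      .parabolicOffset(-rf[ib - 1], -rf[ib], -rf[ib + 1]) * 0.4 * pi / 180

  ct <- cos(theta); st <- sin(theta)
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy

  g <- .binGrid(u, v, h, config$cell)
  Hs <- .smoothNA(.smoothNA(g$H))
  uc <- g$uc; vc <- g$vc

  # midline profile and tail-head depression
  mcols <- which(abs(uc) <= config$midHalfWidth)
  prof <- rowMeans(Hs[, mcols, drop = FALSE], na.rm = TRUE)
  okp <- is.finite(prof)
  if (sum(okp) < 5)
    bcsStop("degenerateInput", "midline height profile is empty")
  cf <- stats::lm.fit(cbind(1, vc[okp], vc[okp]^2), prof[okp])$coefficients
  resid <- prof - (cf[1] + cf[2] * vc + cf[3] * vc^2)
  rsm <- stats::filter(ifelse(okp, resid, 0), rep(1 / 3, 3), sides = 2)
  rsm[!okp] <- NA
  iTail <- which.min(rsm)
  vTail <- vc[iTail]

  # posterior is the nearer end of the body axis to the tail-head depression
  vOk <- vc[apply(!is.na(Hs), 1, any)]
  a <- if ((vTail - min(vOk)) <= (max(vOk) - vTail)) 1 else -1

  wC <- a * (vc - vTail)   # signed: negative = posterior of the tail head

  findPeak <- function(rows, cols, posteriorMost, band) {
    # detrend cells of the band, locate local maxima of the residual raster
    cellIdx <- which(!is.na(Hs[rows, cols, drop = FALSE]), arr.ind = TRUE)
    if (nrow(cellIdx) < 12) return(NULL)
    rr <- rows[cellIdx[, 1]]; cc <- cols[cellIdx[, 2]]
    z <- Hs[cbind(rr, cc)]
    res <- .detrendQuad(uc[cc], vc[rr], z)
    R <- matrix(NA_real_, nrow(Hs), ncol(Hs))
    R[cbind(rr, cc)] <- res - stats::median(res)
    # 8-neighbour local maxima by shifted-matrix comparison
    Rn <- R; Rn[is.na(Rn)] <- -Inf
    nvR <- nrow(Rn); nuR <- ncol(Rn)
    isMaxM <- matrix(TRUE, nvR, nuR)
    for (dv in -1:1) for (du in -1:1) {
      if (dv == 0 && du == 0) next
      sh <- matrix(-Inf, nvR, nuR)
      rs2 <- max(1, 1 + dv):min(nvR, nvR + dv)
      rd2 <- max(1, 1 - dv):min(nvR, nvR - dv)
      cs2 <- max(1, 1 + du):min(nuR, nuR + du)
      cd2 <- max(1, 1 - du):min(nuR, nuR - du)
      sh[rd2, cd2] <- Rn[rs2, cs2]
      isMaxM <- isMaxM & (Rn >= sh)
    }
    # interior cells only: a genuine bump peak has a full 8-neighbourhood;
    # band-boundary cells would otherwise win as spurious maxima
    nFinite <- matrix(0L, nvR, nuR)
    for (dv in -1:1) for (du in -1:1) {
      if (dv == 0 && du == 0) next
      sh <- matrix(0L, nvR, nuR)
      rs2 <- max(1, 1 + dv):min(nvR, nvR + dv)
      rd2 <- max(1, 1 - dv):min(nvR, nvR - dv)
      cs2 <- max(1, 1 + du):min(nuR, nuR + du)
      cd2 <- max(1, 1 - du):min(nuR, nuR - du)
      sh[rd2, cd2] <- is.finite(Rn[rs2, cs2]) & Rn[rs2, cs2] > -Inf
      nFinite <- nFinite + sh
    }
    interior <- nFinite[cbind(rr, cc)] == 8L
    isMax <- isMaxM[cbind(rr, cc)] & interior
    rv <- R[cbind(rr, cc)]
    cand <- which(isMax & rv >= config$prominenceThresh)
    # guard the posterior-most rule against borderline noise maxima: a
    # candidate must also reach 60% of the strongest candidate's prominence
    if (length(cand) > 1)
      cand <- cand[rv[cand] >= 0.6 * max(rv[cand])]
    fail <- length(cand) == 0
    pick <- if (!fail) {
      if (posteriorMost) cand[which.min(a * vc[rr[cand]])]
      else cand[which.max(rv[cand])]
    } else if (any(interior)) which(interior)[which.max(rv[interior])]
    else which.max(rv)
    i0 <- rr[pick]; j0 <- cc[pick]
    prom <- R[i0, j0]
    du <- .parabolicOffset(R[i0, max(1, j0 - 1)], R[i0, j0], R[i0, min(ncol(R), j0 + 1)])
    dv <- .parabolicOffset(R[max(1, i0 - 1), j0], R[i0, j0], R[min(nrow(R), i0 + 1), j0])
    list(u = uc[j0] + du * config$cell, v = vc[i0] + dv * config$cell,
         i = i0, j = j0, R = R, prom = prom, fail = fail)
  }

  confOf <- function(prom, fail)
    if (fail || prom < config$prominenceThresh) 0
    else min(1, (prom - config$prominenceThresh) / config$prominenceThresh)

  hp <- config$hipWidthPrior
  out <- matrix(NA_real_, 4, 3)
  confs <- numeric(4)

  # (b) ischia: posterior band, per lateral half
  pinRows <- which(wC <= config$cell)
  for (s in c(-1, 1)) {
    cols <- which(sign(uc) == s & abs(uc) >= 0.25 * hp & abs(uc) <= 0.75 * hp)
    pk <- findPeak(pinRows, cols, posteriorMost = TRUE, band = "pin")
    if (is.null(pk)) bcsStop("degenerateInput", "ischium search band is empty")
    z <- .localHeight(u, v, h, pk$u, pk$v, fallback = Hs[pk$i, pk$j])
    row <- if (s == -a) 1L else 2L   # animal-left has lateral sign -a
    out[row, ] <- c(pk$u, pk$v, z)
    confs[row] <- confOf(pk$prom, pk$fail)
  }

  # (c) sacrum bases: anterior band, peak then inflection toward the tail
  sacRows <- which(wC > config$cell & wC <= config$sacrumBandMax)
  for (s in c(-1, 1)) {
    cols <- which(sign(uc) == s & abs(uc) >= 0.07 * hp & abs(uc) <= 0.45 * hp)
    pk <- findPeak(sacRows, cols, posteriorMost = FALSE, band = "sacrum")
    if (is.null(pk)) bcsStop("degenerateInput", "sacrum search band is empty")
    # fine longitudinal profile through the sacral peak: raw points within
    # 12 mm laterally, binned at half the raster cell, lightly smoothed, so
    # the inflection is not displaced by the coarse raster smoothing
    fcell <- config$cell / 2
    psel <- abs(u - pk$u) <= 12
    vs <- pk$v - a * config$cell  # fallback: one fine step toward the tail
    if (sum(psel) >= 20) {
      vloc <- v[psel]; hloc <- h[psel]
      iv <- floor(vloc / fcell)  # bins anchored at the centroid: equivariant
      iv <- iv - min(iv)
      vbase <- min(floor(vloc / fcell)) * fcell
      prof <- rowsum(hloc, iv)[, 1] / tabulate(iv + 1L, max(iv) + 1L)[sort(unique(iv)) + 1L]
      pvc <- vbase + (sort(unique(iv)) + 0.5) * fcell
      ok <- is.finite(prof)
      prof <- prof[ok]; pvc <- pvc[ok]
      if (length(prof) >= 9) {
        sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
        nvr <- length(sm)
        d2 <- rep(NA_real_, nvr)
        ii <- 3:(nvr - 2)
        d2[ii] <- as.numeric(sm[ii + 2] - 2 * sm[ii] + sm[ii - 2])
        iPk <- which.min(abs(pvc - pk$v))
        step <- if (a > 0) -1L else 1L    # toward the tail head (posterior)
        iCur <- iPk
        while (iCur + step >= 3 && iCur + step <= nvr - 2) {
          iNext <- iCur + step
          if (is.finite(d2[iCur]) && is.finite(d2[iNext]) &&
              d2[iCur] < 0 && d2[iNext] >= 0) {
            frac <- d2[iCur] / (d2[iCur] - d2[iNext])  # linear zero crossing
            vs <- pvc[iCur] + step * frac * fcell
            break
          }
          iCur <- iNext
        }
      }
    }
    z <- .localHeight(u, v, h, pk$u, vs, fallback = Hs[pk$i, pk$j])
    row <- if (s == -a) 3L else 4L
    out[row, ] <- c(pk$u, vs, z)
    confs[row] <- confOf(pk$prom, pk$fail)
  }

  # plausibility: ischium separation against the hip width prior
  sep <- sqrt(sum((out[1, 1:2] - out[2, 1:2])^2))
  if (sep <= 0 || sep > 1.5 * hp) confs[1:2] <- 0

  # back to the input frame
  world <- cbind(cen[1] + ct * out[, 1] - st * out[, 2],
                 cen[2] + st * out[, 1] + ct * out[, 2],
                 out[, 3])
  if (flip) world <- cbind(world[, 1], -world[, 2], -world[, 3])
  LandmarkSet(world, confidence = confs)
}

#' Per-landmark distance between two landmark sets
#'
#' @param detected,truth [LandmarkSet-class] objects in the same frame.
#' @return named numeric: the four Euclidean distances (mm) plus their mean.
#' @export
landmarkError <- function(detected, truth) {
  stopifnot(is(detected, "LandmarkSet"), is(truth, "LandmarkSet"))
  d <- sqrt(rowSums((detected@coords - truth@coords)^2))
  c(d, mean = mean(d))
}
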