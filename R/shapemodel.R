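## PCA shape space over normalized surfaces and linear regression of the PCA
## coordinates on BCS: training, projection, prediction, persistence.

# coerce a list of NormalizedSurface (or matrices) to an n x p matrix
.surfaceMatrix <- function(surfaces) {
  rows <- lapply(surfaces, function(s) {
    g <- if (is(s, "NormalizedSurface")) s@grid else as.matrix(s)
    if (any(!is.finite(g)))
      bcsStop("invalidArgument",
              "surfaces must be complete (impute before fitting/projecting)")
    as.vector(g)
  })
  p <- unique(vapply(rows, length, integer(1)))
  if (length(p) != 1)
    bcsStop("invalidArgument", "surfaces must share one grid size")
  do.call(rbind, rows)
}

.flatSurface <- function(surface, p) {
  g <- if (is(surface, "NormalizedSurface")) surface@grid else as.matrix(surface)
  if (any(!is.finite(g)))
    bcsStop("invalidArgument", "surface must be complete (impute first)")
  v <- as.vector(g)
  if (length(v) != p)
    bcsStop("invalidArgument", "surface grid size does not match the model")
  v
}

#' Fit the PCA part of a shape model
#'
#' Centres the flattened surfaces by their mean and takes principal
#' components from the singular value decomposition. The retained count `k`
#' is the smallest reaching `varianceThreshold` of the total variance, capped
#' by `kMax` and `n - 1`. Component signs follow the convention that each
#' component's largest-magnitude loading is positive, which makes the fit
#' fully deterministic (two runs on the same data are bit-identical). A
#' dataset with (numerically) zero total variance yields `k = 0`.
#'
#' @param surfaces list of complete [NormalizedSurface-class] objects (or
#'   plain matrices of one common size).
#' @param varianceThreshold fraction of variance to retain.
#' @param kMax hard cap on the component count.
#' @return a [ShapeModel-class] with an empty (all-NA-free, zero-length)
#'   regression part; combine with [fitRegression()] or use
#'   [fitShapeModel()].
#' @export
fitPCA <- function(surfaces, varianceThreshold = 0.95, kMax = 20L) {
  n <- length(surfaces)
  if (n < 3) bcsStop("insufficientData", "need at least 3 surfaces")
  X <- .surfaceMatrix(surfaces)
  p <- ncol(X)
  gdim <- if (is(surfaces[[1]], "NormalizedSurface")) dim(surfaces[[1]]@grid)
          else dim(as.matrix(surfaces[[1]]))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  totVar <- sum(Xc^2) / (n - 1)
  if (totVar < 1e-12) {
    return(new("ShapeModel", meanSurface = mu,
               components = matrix(numeric(0), 0, p),
               explainedVariance = numeric(0),
               coefficients = NA_real_, k = 0L,
               gridDim = as.integer(gdim),
               trainingMeta = list(n_train = n,
                                   variance_threshold = varianceThreshold,
                                   k_max = as.integer(kMax))))
  }
  # spectrum via the n x n Gram matrix (n << p for 150 x 150 grids)
  ee <- eigen(tcrossprod(Xc), symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  lambda <- ev / (n - 1)
  evFrac <- lambda / sum(lambda)
  kVar <- which(cumsum(evFrac) >= varianceThreshold - 1e-12)[1]
  if (is.na(kVar)) kVar <- length(evFrac)
  k <- min(kVar, kMax, n - 1)
  # drop numerically null directions
  keep <- which(lambda[seq_len(k)] > lambda[1] * 1e-12)
  k <- if (length(keep)) max(keep) else 0L
  comp <- if (k > 0) {
    t(crossprod(Xc, ee$vectors[, seq_len(k), drop = FALSE]) %*%
        diag(1 / sqrt(ev[seq_len(k)]), k))
  } else matrix(numeric(0), 0, p)
  if (k > 0) {
    for (i in seq_len(k)) {
      j <- which.max(abs(comp[i, ]))
      if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
    }
  }
  new("ShapeModel", meanSurface = mu, components = comp,
      explainedVariance = evFrac[seq_len(k)],
      coefficients = NA_real_, k = as.integer(k),
      gridDim = as.integer(gdim),
      trainingMeta = list(n_train = n, variance_threshold = varianceThreshold,
                          k_max = as.integer(kMax)))
}

#' Project a surface into the model's PCA coordinates
#'
#' `scores = components %*% (surface - mean)`.
#'
#' @param surface a complete [NormalizedSurface-class] (or matrix).
#' @param model a [ShapeModel-class].
#' @return numeric(k) score vector.
#' @export
projectSurface <- function(surface, model) {
  stopifnot(is(model, "ShapeModel"))
  v <- .flatSurface(surface, length(model@meanSurface))
  as.numeric(model@components %*% (v - model@meanSurface))
}

#' Ordinary least squares of BCS on PCA scores
#'
#' Fits `bcs ~ 1 + scores` by a rank-revealing QR decomposition
#' ([stats::lm.fit()]). With `k = 0` the fit degenerates to the intercept,
#' i.e. the mean of `bcs`.
#'
#' @param scores n x k score matrix (n rows of [projectSurface()] output).
#' @param bcs numeric(n) observed scores.
#' @return numeric(k + 1) coefficients, intercept first.
#' @export
fitRegression <- function(scores, bcs) {
  scores <- as.matrix(scores)
  n <- length(bcs)
  k <- ncol(scores)
  if (nrow(scores) != n)
    bcsStop("invalidArgument", "scores and bcs must have matching rows")
  if (n <= k + 1)
    bcsStop("insufficientData", "need n > k + 1 observations")
  X <- cbind(1, scores)
  fit <- stats::lm.fit(X, bcs)
  if (fit$rank < k + 1)
    bcsStop("numericalRank", "design is rank deficient (duplicated score rows?)")
  unname(fit$coefficients)
}

#' Train a full shape model
#'
#' [fitPCA()] on the training surfaces, projection of each, then
#' [fitRegression()] of the PCA coordinates on the observed BCS.
#'
#' @inheritParams fitPCA
#' @param bcs numeric vector of observed BCS, one per surface.
#' @param seed optional integer recorded in the training metadata.
#' @return a fitted [ShapeModel-class].
#' @export
fitShapeModel <- function(surfaces, bcs, varianceThreshold = 0.95, kMax = 20L,
                          seed = NA_integer_) {
  if (length(surfaces) != length(bcs))
    bcsStop("invalidArgument", "surfaces and bcs must have equal length")
  # the OLS step needs n > k + 1, so the trainer caps k at n - 2
  kMax <- min(as.integer(kMax), length(bcs) - 2L)
  model <- fitPCA(surfaces, varianceThreshold, kMax)
  scores <- t(vapply(surfaces, projectSurface, numeric(model@k), model = model))
  if (model@k == 0) scores <- matrix(numeric(0), length(bcs), 0)
  if (model@k == 1) scores <- matrix(as.numeric(scores), ncol = 1)
  model@coefficients <- fitRegression(scores, bcs)
  model@trainingMeta$seed <- seed
  validObject(model)
  model
}

#' Predict BCS from a normalized surface
#'
#' `intercept + coefficients . scores`, clipped to the 0-5 scale at the API
#' boundary.
#'
#' @param surface a complete [NormalizedSurface-class] (or matrix).
#' @param model a fitted [ShapeModel-class].
#' @return predicted BCS in `[0, 5]`.
#' @export
predictBCS <- function(surface, model) {
  stopifnot(is(model, "ShapeModel"))
  if (anyNA(model@coefficients))
    bcsStop("stateError", "model has no regression part; call fitShapeModel()")
  s <- projectSurface(surface, model)
  raw <- model@coefficients[1] + sum(model@coefficients[-1] * s)
  min(5, max(0, raw))
}

#' Root mean square error of prediction
#'
#' `sqrt(mean((pred - truth)^2))` in BCS points.
#'
#' @param pred,truth numeric vectors of equal length (n >= 1).
#' @return RMSEP.
#' @export
evaluateRMSEP <- function(pred, truth) {
  if (length(pred) != length(truth))
    bcsStop("invalidArgument", "pred and truth must have equal length")
  if (length(pred) < 1) bcsStop("invalidArgument", "need at least one pair")
  sqrt(mean((pred - truth)^2))
}

## Persistence: one container file = magic, JSON header, float64 arrays
## (little-endian), CRC-32 of the array bytes recorded in the header.

.MODEL_MAGIC <- "BCS3DMDL"
.MODEL_SCHEMA <- 1L

#' Save and load shape models
#'
#' Single-file container: an 8-byte magic, a length-prefixed JSON header
#' (schema version, k, grid size, explained variance, coefficients, training
#' metadata, array checksum) and the mean surface plus component rows as
#' little-endian float64. The round trip is exact at float64; a mismatched
#' schema version or checksum raises a format error.
#'
#' @param model a [ShapeModel-class].
#' @param path file path.
#' @return `loadModel` returns the [ShapeModel-class]; `saveModel`
#'   (invisibly) the path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  # every numeric array lives in the float64 section so the round trip is
  # exact to the last ulp; the JSON header carries structure and metadata
  arr <- c(model@meanSurface, as.vector(t(model@components)),
           model@explainedVariance, model@coefficients)
  arrRaw <- writeBin(arr, raw(), size = 8, endian = "little")
  hdr <- list(schema = .MODEL_SCHEMA, k = model@k,
              grid_dim = model@gridDim,
              p = length(model@meanSurface),
              n_coef = length(model@coefficients),
              training_meta = model@trainingMeta,
              checksum = .crc32Cpp(arrRaw))
  hdrRaw <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA,
                                       null = "null", na = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.MODEL_MAGIC), con)
  writeBin(length(hdrRaw), con, size = 4, endian = "little")
  writeBin(hdrRaw, con)
  writeBin(arrRaw, con)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) bcsStop("formatError", sprintf("no such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8))
  if (!identical(magic, .MODEL_MAGIC))
    bcsStop("formatError", sprintf("not a shape model file: %s", path))
  hlen <- readBin(con, "integer", size = 4, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  if (!identical(as.integer(hdr$schema), .MODEL_SCHEMA))
    bcsStop("formatError",
            sprintf("unsupported model schema version %s: %s", hdr$schema, path))
  p <- as.integer(hdr$p); k <- as.integer(hdr$k)
  nCoef <- as.integer(hdr$n_coef)
  nArr <- p * (k + 1L) + k + nCoef
  arrRaw <- readBin(con, "raw", n = 8L * nArr)
  if (length(arrRaw) != 8L * nArr)
    bcsStop("formatError", sprintf("model arrays truncated: %s", path))
  if (!isTRUE(all.equal(.crc32Cpp(arrRaw), as.numeric(hdr$checksum))))
    bcsStop("formatError", sprintf("model checksum mismatch: %s", path))
  arr <- readBin(arrRaw, "double", n = nArr, size = 8, endian = "little")
  mu <- arr[seq_len(p)]
  comp <- if (k > 0)
    matrix(arr[p + seq_len(p * k)], nrow = k, byrow = TRUE)
  else matrix(numeric(0), 0, p)
  ev <- arr[p * (k + 1L) + seq_len(k)]
  cf <- arr[p * (k + 1L) + k + seq_len(nCoef)]
  tm <- as.list(hdr$training_meta)
  new("ShapeModel", meanSurface = mu, components = comp,
      explainedVariance = as.numeric(ev), coefficients = as.numeric(cf),
      k = k, gridDim = as.integer(hdr$grid_dim), trainingMeta = tm)
}
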