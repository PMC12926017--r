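#' Derive a stage seed from a run seed
#'
#' All randomness in the package flows from one integer run seed. Stage- or
#' animal-level seeds are split off deterministically by a documented affine
#' counter scheme, `(69069 * seed + 12345 + 97531 * k) mod (2^31 - 1)`,
#' evaluated exactly in double precision (all intermediates stay below 2^53).
#'
#' @param seed integer run seed.
#' @param k non-negative integer counter (stage or item index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((69069 * s + 12345 + 97531 * as.numeric(k)) %% 2147483647)
}

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Rotation matrices about the coordinate axes
#'
#' @param theta angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rotZ <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @rdname rotZ
#' @export
rotX <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rotZ
#' @export
rotY <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Apply a rigid transform to a set of points
#'
#' Computes `p %*% t(R) + t` row-wise, i.e. `R p + t` per point.
#'
#' @param points N x 3 numeric matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return transformed N x 3 matrix.
#' @export
transformPoints <- function(points, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  sweep(points %*% t(rotation), 2, translation, "+")
}

# stop() with a classed condition so callers can distinguish error families
bcsStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "bcs3dError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
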