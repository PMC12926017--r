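## Classical LOESS, implemented from first principles.
##
## For each evaluation point x0: take the q = ceil(span * n) nearest
## observations, weight them by the tricube kernel w = (1 - (d/dmax)^3)^3
## with dmax the largest of the q distances, fit a weighted polynomial of the
## requested degree in (x - x0), and read the fitted value at x0 (the
## intercept). No robustness iterations are applied. The local solve uses the
## weighted normal equations; the test oracle re-solves each point with an
## independent weighted-least-squares routine.

.loessFitAt <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- ceiling(span * n)
  if (q < degree + 2)
    bcsStop("invalidArgument",
            sprintf("span %.3g too small for degree %d at n = %d", span, degree, n))
  d <- abs(x - x0)
  idx <- order(d, x)[seq_len(q)]   # secondary key makes ties deterministic
  dmax <- d[idx[q]]
  if (dmax <= 0) return(mean(y[idx]))
  w <- (1 - pmin(1, d[idx] / dmax)^3)^3
  dx <- x[idx] - x0
  X <- outer(dx, 0:degree, `^`)
  A <- crossprod(X, w * X)
  b <- crossprod(X, w * y[idx])
  beta <- solve(A, b)
  beta[1, 1]
}

#' LOESS smoothing of a longitudinal series
#'
#' Locally estimated scatterplot smoothing with tricube weights and a local
#' polynomial of degree 1 or 2; defaults span 0.75, degree 2. Fitted values
#' are returned at the observation points.
#'
#' @param x strictly increasing numeric abscissae (e.g. days).
#' @param y numeric responses.
#' @param span neighbourhood fraction in (0, 1]; `ceil(span * n)` points
#'   enter each local fit.
#' @param degree local polynomial degree, 1 or 2.
#' @return a [SmoothCurve-class].
#' @export
loessSmooth <- function(x, y, span = 0.75, degree = 2L) {
  n <- length(x)
  if (length(y) != n) bcsStop("invalidArgument", "x and y must have equal length")
  if (n < degree + 2)
    bcsStop("invalidArgument", sprintf("need at least %d points", degree + 2))
  if (any(diff(x) <= 0))
    bcsStop("invalidArgument", "x must be strictly increasing")
  if (span <= 0 || span > 1) bcsStop("invalidArgument", "span must lie in (0, 1]")
  if (!degree %in% c(1, 2)) bcsStop("invalidArgument", "degree must be 1 or 2")
  fitted <- vapply(x, function(x0) .loessFitAt(x, y, x0, span, degree), numeric(1))
  new("SmoothCurve", x = as.numeric(x), fitted = fitted,
      span = span, degree = as.integer(degree))
}

#' Evaluate the LOESS smoother at arbitrary abscissae
#'
#' Runs the same local fit centred on each requested point (the smoother is
#' defined pointwise, so evaluation off the observation grid is exact, not an
#' interpolation of fitted values).
#'
#' @inheritParams loessSmooth
#' @param xout numeric points at which to evaluate.
#' @return numeric fitted values at `xout`.
#' @export
loessPredict <- function(x, y, xout, span = 0.75, degree = 2L) {
  n <- length(x)
  if (length(y) != n) bcsStop("invalidArgument", "x and y must have equal length")
  if (any(diff(x) <= 0)) bcsStop("invalidArgument", "x must be strictly increasing")
  vapply(xout, function(x0) .loessFitAt(x, y, x0, span, degree), numeric(1))
}
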