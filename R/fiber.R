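#' Resample a fiber to m points equally spaced in arc length
#'
#' Reparameterizes a 3-D polyline by arc length and places exactly `m` points
#' at equal arc-length intervals, preserving both endpoints exactly. All
#' fibers and centroids must share one point count so that point-wise
#' correspondence (and hence the Gaussian curve likelihood) is defined.
#'
#' @param fiber n x 3 numeric matrix, n >= 2, with positive total arc length.
#' @param m target point count (>= 2).
#' @return m x 3 numeric matrix.
#' @examples
#' f <- cbind(seq(0, 10, length.out = 4), 0, 0)
#' resampleFiber(f, 11)[, 1]   # 0, 1, ..., 10
#' @export
resampleFiber <- function(fiber, m) {
  fiber <- stopIfNot3(fiber, "fiber")
  if (nrow(fiber) < 2) stop("fiber must have at least 2 points")
  if (m < 2) stop("m must be >= 2")
  seg <- sqrt(rowSums((fiber[-1, , drop = FALSE] - fiber[-nrow(fiber), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate geometry: fiber has zero arc length")
  # drop zero-length segments so the arc-length parameter is strictly increasing
  keep <- c(TRUE, seg > 0)
  pts <- fiber[keep, , drop = FALSE]
  s <- c(0, cumsum(seg[seg > 0]))
  target <- seq(0, total, length.out = m)
  out <- vapply(1:3, function(d) approx(s, pts[, d], xout = target)$y, numeric(m))
  out <- matrix(out, ncol = 3)
  out[1, ] <- fiber[1, ]        # endpoints exact, immune to rounding in approx
  out[m, ] <- fiber[nrow(fiber), ]
  out
}

#' Orient a fiber consistently with a reference curve
#'
#' Streamline files carry no canonical direction, so point-wise
#' correspondence between a fiber and a centroid is ambiguous up to reversal.
#' Returns the fiber either as stored or point-reversed, whichever has the
#' smaller mean corresponding-point distance to `reference`; ties keep the
#' stored order.
#'
#' @param fiber,reference m x 3 matrices with equal point counts.
#' @return list with `points` (the oriented m x 3 matrix) and `reversed`
#'   (logical flag).
#' @export
orientFiber <- function(fiber, reference) {
  if (nrow(fiber) != nrow(reference)) stop("point counts differ")
  dFwd <- sum((fiber - reference)^2)
  rev <- fiber[nrow(fiber):1, , drop = FALSE]
  dRev <- sum((rev - reference)^2)
  if (dRev < dFwd) list(points = rev, reversed = TRUE)
  else list(points = fiber, reversed = FALSE)
}

#' Mean corresponding-point distance between two fibers
#'
#' The curve-to-curve distance used throughout: the mean Euclidean distance
#' over corresponding points of two equally resampled, orientation-normalized
#' fibers (in voxels). This is the distance implied by the isotropic Gaussian
#' curve model and makes the coherence metrics well defined. It is a
#' pseudometric: symmetric, non-negative, zero iff the curves are identical.
#'
#' @param a,b m x 3 matrices with equal point counts.
#' @return single non-negative number (voxels).
#' @export
fiberDistance <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("point counts differ")
  mean(sqrt(rowSums((a - b)^2)))
}

# Resample only when the stored point count differs from m: fibers that
# already carry m points are used as stored, so point-wise correspondence is
# whatever the file (or generator) defined.
ensurePoints <- function(fiber, m) {
  if (nrow(fiber) == m) fiber else resampleFiber(fiber, m)
}

# Stack a list of m x 3 fibers into a J x 3m matrix (x1 y1 z1 x2 ...).
# The internal layout the vectorized E-step operates on.
stackFibers <- function(fiberList) {
  J <- length(fiberList)
  m <- nrow(fiberList[[1]])
  out <- matrix(0, J, 3L * m)
  for (j in seq_len(J)) out[j, ] <- as.double(t(fiberList[[j]]))
  out
}

# Reverse point order in stacked layout
reverseStacked <- function(X, m) {
  idx <- as.vector(vapply(m:1, function(i) (3L * (i - 1L)) + 1:3, integer(3)))
  X[, idx, drop = FALSE]
}

flatten <- function(mu) as.double(t(mu))
unflatten <- function(v) matrix(v, ncol = 3, byrow = TRUE)
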