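#' Least-squares rigid alignment of corresponding point sets
#'
#' Orthogonal Procrustes with translation (Kabsch): finds the rotation R and
#' translation t minimizing the sum of squared distances between
#' `R source + t` and `target` over corresponding rows.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @param weights optional non-negative per-point weights.
#' @return A [RigidTransform-class].
#' @export
fitRigid <- function(source, target, weights = NULL) {
  source <- stopIfNot3(source); target <- stopIfNot3(target)
  if (nrow(source) != nrow(target)) stop("point counts differ")
  if (nrow(source) < 3) stop("need at least 3 point pairs")
  w <- if (is.null(weights)) rep(1, nrow(source)) else weights / sum(weights) * nrow(source)
  cs <- colSums(source * w) / sum(w)
  ct <- colSums(target * w) / sum(w)
  S <- sweep(source, 2, cs); T <- sweep(target, 2, ct)
  H <- crossprod(S * w, T)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) stop("degenerate geometry: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new("RigidTransform", rotation = R, translation = as.numeric(ct - R %*% cs))
}

# 3-D thin-plate-spline kernel: U(r) = r (biharmonic in 3-D)
tpsKernel <- function(a, b) {
  n <- nrow(a); k <- nrow(b)
  d2 <- outer(rowSums(a^2), rep(1, k)) + outer(rep(1, n), rowSums(b^2)) -
    2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a 3-D thin-plate-spline transform
#'
#' Closed-form weighted regularized TPS with kernel U(r) = r. Minimizes the
#' weighted sum of squared residuals plus `lambda` times the bending energy;
#' `lambda = 0` interpolates the control points exactly, and as
#' `lambda -> Inf` the warp converges to the weighted least-squares affine
#' fit (the affine part lies in the kernel's null space).
#'
#' @param source n x 3 control points (n >= 4, non-coplanar).
#' @param target n x 3 corresponding target points.
#' @param lambda regularization weight (>= 0). `NULL` picks
#'   `0.01 * bounding-box diagonal` of the source points, a mild default that
#'   discourages folding when control points are few.
#' @param weights optional positive per-point weights; heavier points
#'   dominate the fit.
#' @return A [TPSTransform-class].
#' @export
fitTPS <- function(source, target, lambda = NULL, weights = NULL) {
  source <- stopIfNot3(source); target <- stopIfNot3(target)
  if (nrow(source) != nrow(target)) stop("point counts differ")
  n <- nrow(source)
  if (n < 4) stop("need at least 4 control points")
  if (is.null(lambda)) {
    bb <- apply(source, 2, range)
    lambda <- 0.01 * sqrt(sum((bb[2, ] - bb[1, ])^2))
  }
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("weights must be > 0 (drop zero-weight points)")
  K <- tpsKernel(source, source)
  P <- cbind(1, source)
  A <- rbind(cbind(K + lambda * diag(1 / weights, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular TPS system (control points may be coplanar); ",
         "add points or increase lambda: ", conditionMessage(e)))
  new("TPSTransform", controls = source, W = sol[1:n, , drop = FALSE],
      A = sol[(n + 1):(n + 4), , drop = FALSE], lambda = lambda)
}

#' @describeIn warpPoints rigid map `R p + t`.
#' @export
setMethod("warpPoints", "RigidTransform", function(transform, points) {
  points <- stopIfNot3(points)
  sweep(points %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @describeIn warpPoints thin-plate-spline map
#'   `U(p, controls) W + [1 p] A`.
#' @export
setMethod("warpPoints", "TPSTransform", function(transform, points) {
  points <- stopIfNot3(points)
  tpsKernel(points, transform@controls) %*% transform@W +
    cbind(1, points) %*% transform@A
})

#' @describeIn warpPoints `NULL` acts as the identity transform.
#' @export
setMethod("warpPoints", "NULL", function(transform, points) {
  stopIfNot3(points)
})

# Warp every fiber of a stacked J x 3m matrix.
warpStacked <- function(transform, X, m) {
  if (is.null(transform)) return(X)
  J <- nrow(X)
  pts <- matrix(as.double(t(X)), ncol = 3, byrow = TRUE)  # (J*m) x 3
  wp <- warpPoints(transform, pts)
  matrix(as.double(t(wp)), nrow = J, byrow = TRUE)
}

#' Serialize / restore a transform as a plain list
#'
#' Converts a rigid or TPS transform to a JSON-friendly list of numeric
#' fields, and back. Used by [writeOutputs()].
#'
#' @param transform a transform object or (for restore) a list.
#' @return `transformToList`: a list; `transformFromList`: a transform.
#' @export
transformToList <- function(transform) {
  if (is.null(transform)) return(list(type = "identity"))
  if (is(transform, "RigidTransform"))
    return(list(type = "rigid", rotation = transform@rotation,
                translation = transform@translation))
  list(type = "tps", controls = transform@controls, W = transform@W,
       A = transform@A, lambda = transform@lambda)
}

#' @rdname transformToList
#' @param x list produced by `transformToList` (or parsed from JSON).
#' @export
transformFromList <- function(x) {
  asMat <- function(v) if (is.matrix(v)) v else do.call(rbind, v)
  switch(x$type,
    identity = NULL,
    rigid = new("RigidTransform", rotation = asMat(x$rotation),
                translation = as.numeric(x$translation)),
    tps = new("TPSTransform", controls = asMat(x$controls), W = asMat(x$W),
              A = asMat(x$A), lambda = as.numeric(x$lambda)),
    stop("unknown transform type: ", x$type))
}
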