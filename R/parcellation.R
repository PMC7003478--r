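#' Build per-ROI Euclidean distance fields
#'
#' Precomputes, for every label l = 1..L, the exact Euclidean distance
#' transform of the binary mask of ROI l (distance in voxels from each voxel
#' center to the nearest voxel of the ROI). Evaluating the terminal-projection
#' likelihood then reduces to a field lookup instead of a nearest-point
#' search over the ROI.
#'
#' @param parc a [Parcellation-class].
#' @return A [DistanceFields-class] object.
#' @export
buildDistanceFields <- function(parc) {
  lab <- parc@labels
  dims <- dim(lab)
  fields <- vector("list", parc@L)
  names(fields) <- as.character(seq_len(parc@L))
  for (l in seq_len(parc@L)) {
    mask <- lab == l
    if (!any(mask)) stop("label ", l, " has no voxels; cannot build its distance field")
    d2 <- .edt3d(as.integer(mask), as.integer(dims))
    fields[[l]] <- sqrt(d2)
  }
  new("DistanceFields", fields = fields, dim = as.integer(dims))
}

# Trilinear interpolation of a 3-D field at continuous 0-based voxel
# coordinates, clamped to the grid. points: n x 3. Vectorized.
interpField <- function(field, points, dims) {
  n <- nrow(points)
  p <- pmin(pmax(points, 0), matrix(rep(dims - 1L, each = n), n, 3))
  p0 <- floor(p)
  fr <- p - p0
  p0 <- pmin(p0, matrix(rep(dims - 2L, each = n), n, 3))  # keep p0+1 in range
  p0[p0 < 0] <- 0
  fr <- p - p0
  i <- p0[, 1]; j <- p0[, 2]; k <- p0[, 3]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  base <- i + j * nx + k * nxy + 1
  c000 <- field[base];            c100 <- field[base + 1]
  c010 <- field[base + nx];       c110 <- field[base + nx + 1]
  c001 <- field[base + nxy];      c101 <- field[base + nxy + 1]
  c011 <- field[base + nx + nxy]; c111 <- field[base + nx + nxy + 1]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Query a distance field at continuous points
#'
#' Trilinear interpolation of the per-label distance transform at continuous,
#' 0-based voxel coordinates; coordinates outside the grid are clamped to the
#' boundary rather than extrapolated.
#'
#' @param dist a [DistanceFields-class].
#' @param points n x 3 matrix (or length-3 vector) of query points.
#' @param label ROI label (integer in 1..L).
#' @return numeric vector of distances (voxels).
#' @export
queryDistance <- function(dist, points, label) {
  points <- stopIfNot3(points, "query point")
  f <- dist@fields[[as.character(label)]]
  if (is.null(f)) stop("no distance field for label ", label)
  interpField(f, points, dist@dim)
}

# Distances from points to ALL labels at once: n x L matrix.
queryDistanceAll <- function(dist, points) {
  points <- stopIfNot3(points, "query point")
  vapply(dist@fields, function(f) interpField(f, points, dist@dim),
         numeric(nrow(points)))
}

#' Log-likelihood of a fiber terminal belonging to an ROI
#'
#' Gaussian terminal-projection model: the terminal r is projected to its
#' closest point in ROI l, and the likelihood is an isotropic 3-D Gaussian in
#' that projection distance,
#' \deqn{\log p(r \mid l) = -\tfrac{3}{2}\log(2\pi\sigma_{ROI}^2)
#'   - \phi_l(r)^2 / (2\sigma_{ROI}^2),}
#' where \eqn{\phi_l} is the precomputed distance transform of ROI l.
#' sigmaRoi encodes the combined registration and tracking uncertainty at
#' fiber terminals: small values trust the label mapping, large values relax
#' the anatomical constraint.
#'
#' @param dist a [DistanceFields-class].
#' @param points n x 3 matrix (or length-3 vector) of terminal coordinates.
#' @param label ROI label.
#' @param sigmaRoi terminal standard deviation in voxels (> 0).
#' @return numeric vector of log-densities.
#' @export
roiLogLikelihood <- function(dist, points, label, sigmaRoi) {
  if (sigmaRoi <= 0) stop("sigmaRoi must be > 0")
  phi <- queryDistance(dist, points, label)
  -1.5 * log(2 * pi * sigmaRoi^2) - phi^2 / (2 * sigmaRoi^2)
}

#' Best terminal-to-ROI correspondence for a bundle's ROI pair
#'
#' A fiber's two terminals (r1, r2) can correspond to the bundle's ROI pair
#' (l1, l2) in either order; the model takes the pairing with the greater
#' joint terminal likelihood. Ties keep the pairing (r1 -> l1, r2 -> l2).
#'
#' @param dist a [DistanceFields-class].
#' @param r1,r2 length-3 terminal coordinates.
#' @param l1,l2 distinct ROI labels.
#' @param sigmaRoi terminal standard deviation (voxels).
#' @return list with `logLik` (the max of the two pairings' summed terminal
#'   log-likelihoods) and `swapped` (TRUE if the winning pairing is
#'   r1 -> l2, r2 -> l1).
#' @export
terminalPairLogLikelihood <- function(dist, r1, r2, l1, l2, sigmaRoi) {
  if (l1 == l2) stop("invalid bundle key: l1 == l2 (self-pairs do not exist)")
  a <- roiLogLikelihood(dist, r1, l1, sigmaRoi) + roiLogLikelihood(dist, r2, l2, sigmaRoi)
  b <- roiLogLikelihood(dist, r1, l2, sigmaRoi) + roiLogLikelihood(dist, r2, l1, sigmaRoi)
  if (b > a) list(logLik = b, swapped = TRUE) else list(logLik = a, swapped = FALSE)
}

#' Closest ROI pair for a fiber's terminals
#'
#' Returns the unordered pair of labels whose ROIs are nearest (in the
#' distance-transform sense) to the two terminals. Argmin ties go to the
#' smaller label. When both terminals are closest to the same ROI (the model
#' has no self-pair bundle), the terminal with the larger within-label
#' distance is moved to its second-closest label.
#'
#' @param dist a [DistanceFields-class].
#' @param r1,r2 length-3 terminal coordinates.
#' @return integer vector (l1, l2) with l1 < l2.
#' @export
closestRoiPair <- function(dist, r1, r2) {
  d <- queryDistanceAll(dist, rbind(r1, r2))  # 2 x L
  if (ncol(d) < 2) stop("need at least 2 labels")
  a1 <- which.min(d[1, ]); a2 <- which.min(d[2, ])
  if (a1 == a2) {
    # break the degeneracy: reassign the worse-matching terminal
    if (d[1, a1] > d[2, a2]) {
      d1 <- d[1, ]; d1[a1] <- Inf; a1 <- which.min(d1)
    } else {
      d2 <- d[2, ]; d2[a2] <- Inf; a2 <- which.min(d2)
    }
  }
  unname(sort(c(a1, a2)))
}
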