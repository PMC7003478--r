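#' Canonical bundle key for an ROI pair
#'
#' Bundles are indexed by unordered ROI pairs; keys are stored canonically as
#' `"l1-l2"` with l1 < l2 (the pair (l2, l1) names the same bundle). Self
#' pairs are invalid: no bundle connects an ROI to itself.
#'
#' @param l1,l2 distinct positive integer labels.
#' @return single character key.
#' @seealso [keyLabels()]
#' @export
bundleKey <- function(l1, l2) {
  if (any(l1 == l2)) stop("invalid bundle key: l1 == l2")
  paste0(pmin(l1, l2), "-", pmax(l1, l2))
}

#' Labels of a bundle key
#' @param key character key "l1-l2".
#' @return integer vector (l1, l2).
#' @export
keyLabels <- function(key) {
  as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
}

#' Gaussian curve log-likelihood of a fiber under a bundle centroid
#'
#' The bundle shape model: fiber points are independent isotropic Gaussians
#' around the corresponding centroid points,
#' \deqn{\log p(x \mid \mu) = \sum_{i=1}^{m}\Big[-\tfrac{3}{2}
#'   \log(2\pi\sigma_b^2) - \lVert x_i - \mu_i \rVert^2/(2\sigma_b^2)\Big].}
#' A single sigma is shared by all points of all bundles; small bundles make
#' point-specific covariances unstable to estimate. The fiber must already be
#' orientation-normalized to the centroid (see [orientFiber()]).
#'
#' @param fiber,centroid m x 3 matrices with equal point counts.
#' @param sigmaBundle isotropic standard deviation in voxels (> 0).
#' @return log-density (single number).
#' @export
fiberShapeLogLikelihood <- function(fiber, centroid, sigmaBundle) {
  if (nrow(fiber) != nrow(centroid)) stop("point counts differ")
  if (sigmaBundle <= 0) stop("sigmaBundle must be > 0")
  m <- nrow(fiber)
  -1.5 * m * log(2 * pi * sigmaBundle^2) -
    sum((fiber - centroid)^2) / (2 * sigmaBundle^2)
}

#' Joint bundle log-likelihood of a fiber (shape x terminal projection)
#'
#' The gray-matter-constrained bundle likelihood: the product (sum in log
#' space) of the Gaussian curve term against the bundle centroid and the
#' terminal-projection term of the fiber's two endpoints against the bundle's
#' ROI pair, with the terminal-to-ROI correspondence chosen to maximize the
#' terminal term. Orientation for the shape term is resolved against the
#' centroid (distance-minimizing), independently of the terminal pairing.
#'
#' @param fiber m x 3 matrix (any stored orientation; normalized internally).
#' @param key canonical bundle key present in `model`.
#' @param model a [BundleModel-class].
#' @param dist a [DistanceFields-class].
#' @return list with `logLik`, `reversed` (orientation used for the shape
#'   term), and `swapped` (winning terminal pairing).
#' @export
jointLogLikelihood <- function(fiber, key, model, dist) {
  mu <- model@centroids[[key]]
  if (is.null(mu)) stop("unknown bundle key: ", key)
  o <- orientFiber(fiber, mu)
  shape <- fiberShapeLogLikelihood(o$points, mu, model@sigmaBundle)
  ll <- keyLabels(key)
  r1 <- o$points[1, ]; r2 <- o$points[nrow(o$points), ]
  term <- terminalPairLogLikelihood(dist, r1, r2, ll[1], ll[2], model@sigmaRoi)
  list(logLik = shape + term$logLik, reversed = o$reversed, swapped = term$swapped)
}
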