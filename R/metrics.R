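#' Mean inbundle variation (MIV)
#'
#' Bundle coherence: the mean distance of fibers to their assigned bundle
#' centroid, \eqn{MIV = \frac{1}{J}\sum_j |x_j - \mu_{\phi(j)}|}, where
#' \eqn{|\cdot|} is [fiberDistance()] after orientation normalization and J
#' counts assigned fibers (unassigned fibers are excluded and reported).
#'
#' @param fiberSet a [FiberSet-class] (fibers are resampled to match the
#'   centroids).
#' @param assignment character vector of bundle keys (NA = unassigned).
#' @param cents named list of centroid matrices (or a [BundleModel-class]).
#' @return number of voxels; attribute `"nExcluded"` counts skipped fibers.
#' @export
meanInbundleVariation <- function(fiberSet, assignment, cents) {
  if (is(cents, "BundleModel")) cents <- cents@centroids
  m <- nrow(cents[[1]])
  fl <- lapply(fibers(fiberSet), ensurePoints, m = m)
  ok <- which(!is.na(assignment) & assignment %in% names(cents))
  if (!length(ok)) stop("no assigned fibers with centroids")
  d <- vapply(ok, function(j) {
    mu <- cents[[assignment[j]]]
    fiberDistance(orientFiber(fl[[j]], mu)$points, mu)
  }, 1)
  structure(mean(d), nExcluded = length(fl) - length(ok))
}

#' Mean end-to-ROI distance (MED)
#'
#' Anatomical consistency: the mean, over assigned fibers, of the summed
#' distances of the two fiber terminals to the ROI pair of the assigned
#' bundle, \eqn{MED = \frac{1}{J}\sum_j [\phi_{l1}(r1_j) + \phi_{l2}(r2_j)]},
#' with the terminal-to-ROI correspondence that wins the terminal-pairing
#' likelihood.
#'
#' @inheritParams meanInbundleVariation
#' @param dist a [DistanceFields-class].
#' @param m resample point count used to locate terminals (default 20).
#' @return number of voxels; attribute `"nExcluded"` as in MIV.
#' @export
meanEndToRoiDistance <- function(fiberSet, assignment, dist, m = 20L) {
  ok <- which(!is.na(assignment))
  if (!length(ok)) stop("no assigned fibers")
  d <- vapply(ok, function(j) {
    f <- fibers(fiberSet)[[j]]
    r1 <- f[1, ]; r2 <- f[nrow(f), ]
    lab <- keyLabels(assignment[j])
    p11 <- queryDistance(dist, r1, lab[1]); p22 <- queryDistance(dist, r2, lab[2])
    p12 <- queryDistance(dist, r1, lab[2]); p21 <- queryDistance(dist, r2, lab[1])
    # winning correspondence maximizes the Gaussian product = min sum of squares
    if (p12^2 + p21^2 < p11^2 + p22^2) p12 + p21 else p11 + p22
  }, 1)
  structure(mean(d), nExcluded = length(assignment) - length(ok))
}

#' Mean bundle centroid difference (MBCD)
#'
#' Cross-subject consistency: the mean distance between subject-specific
#' bundle centroids (in common space) and the group centroid,
#' \eqn{MBCD = \frac{1}{KS}\sum_k \sum_s |\mu^s_k - \mu_k|}, averaged over
#' the (subject, bundle) pairs for which both centroids exist.
#'
#' @param subjCentsCommon list (one per subject) of named lists of centroid
#'   matrices already mapped into the common space.
#' @param commonCents named list of group centroid matrices.
#' @return number of voxels.
#' @export
meanBundleCentroidDifference <- function(subjCentsCommon, commonCents) {
  tot <- 0; n <- 0L
  for (s in seq_along(subjCentsCommon)) {
    for (k in intersect(names(subjCentsCommon[[s]]), names(commonCents))) {
      mu <- commonCents[[k]]
      mus <- orientFiber(subjCentsCommon[[s]][[k]], mu)$points
      tot <- tot + fiberDistance(mus, mu)
      n <- n + 1L
    }
  }
  if (n == 0L) stop("no shared bundles between subjects and group model")
  tot / n
}

#' Groupwise mean inbundle variation (GMIV)
#'
#' Coherence of the group model: the average distance of all subjects'
#' (transform-warped) fibers to their assigned common bundle centroids,
#' normalized by the total number of assigned fibers.
#'
#' @param fiberSets list of [FiberSet-class].
#' @param assignments list of per-subject key vectors (NA = unassigned).
#' @param commonCents named list of group centroids (or [BundleModel-class]).
#' @param transforms list of per-subject transforms (NULL = identity).
#' @return number of voxels; attribute `"nExcluded"`.
#' @export
groupwiseMIV <- function(fiberSets, assignments, commonCents, transforms = NULL) {
  if (is(commonCents, "BundleModel")) commonCents <- commonCents@centroids
  m <- nrow(commonCents[[1]])
  tot <- 0; n <- 0L; excl <- 0L
  for (s in seq_along(fiberSets)) {
    fl <- lapply(fibers(fiberSets[[s]]), ensurePoints, m = m)
    tr <- if (is.null(transforms)) NULL else transforms[[s]]
    a <- assignments[[s]]
    for (j in seq_along(fl)) {
      if (is.na(a[j]) || is.null(commonCents[[a[j]]])) { excl <- excl + 1L; next }
      x <- warpPoints(tr, fl[[j]])
      mu <- commonCents[[a[j]]]
      tot <- tot + fiberDistance(orientFiber(x, mu)$points, mu)
      n <- n + 1L
    }
  }
  if (n == 0L) stop("no assigned fibers")
  structure(tot / n, nExcluded = excl)
}

#' Discard bundles that are inconsistent across subjects
#'
#' A bundle is retained only if it is present in every subject and the mean
#' distance of its per-subject centroids (in common space) from the group
#' centroid is at most `threshold` (2.5 voxels by default; strictly greater
#' discards, equality retains). Uncertain tracking and residual
#' misregistration can produce bundles for connections that do not exist;
#' cross-subject consistency is the filter.
#'
#' @inheritParams meanBundleCentroidDifference
#' @param threshold consistency threshold in voxels.
#' @return character vector of retained keys; attribute `"discarded"` is a
#'   named numeric of discarded keys and their mean differences.
#' @export
pruneInconsistentBundles <- function(subjCentsCommon, commonCents, threshold = 2.5) {
  S <- length(subjCentsCommon)
  keep <- character(); dropped <- numeric()
  for (k in names(commonCents)) {
    present <- vapply(subjCentsCommon, function(x) !is.null(x[[k]]), TRUE)
    if (!all(present)) { dropped[k] <- NA_real_; next }
    mu <- commonCents[[k]]
    dbar <- mean(vapply(subjCentsCommon, function(x)
      fiberDistance(orientFiber(x[[k]], mu)$points, mu), 1))
    if (dbar > threshold) dropped[k] <- dbar else keep <- c(keep, k)
  }
  structure(orderKeys(keep), discarded = dropped)
}

#' Metrics for a group bundling result
#'
#' Convenience wrapper computing GMIV and MBCD (plus per-bundle counts) from
#' a [runGroupEM()] result, mapping each subject's native centroids into the
#' common space with its transform.
#'
#' @param result output of [runGroupEM()].
#' @param fiberSets the fiber sets the result was computed from.
#' @return list with `gmiv`, `mbcd`, `counts` (fibers per bundle), and
#'   `subjCentsCommon`.
#' @export
groupMetrics <- function(result, fiberSets) {
  common <- result$group@model@centroids
  trs <- result$group@transforms
  subjCentsCommon <- lapply(seq_along(result$subjCents), function(s) {
    lapply(result$subjCents[[s]]$centroids, function(mu) warpPoints(trs[[s]], mu))
  })
  gmiv <- groupwiseMIV(fiberSets, result$assignments, common, trs)
  mbcd <- meanBundleCentroidDifference(subjCentsCommon, common)
  counts <- table(factor(unlist(result$assignments), levels = names(common)))
  list(gmiv = as.numeric(gmiv), mbcd = mbcd,
       counts = counts, subjCentsCommon = subjCentsCommon)
}
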