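# Center of mass (0-based voxel coords) of every ROI: L x 3.
roiCenters <- function(parc) {
  lab <- parc@labels
  out <- matrix(NA_real_, parc@L, 3)
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  for (d in 1:3) out[, d] <- tapply(idx[, d] - 1, l, mean)[as.character(seq_len(parc@L))]
  out
}

#' Initialize groupwise bundling
#'
#' Rigidly pre-aligns every subject to the common (label-grid) space, then
#' pools the rigidly warped fibers to form initial common centroids. The
#' rigid fit anchors each subject to the parcellation: source points are the
#' endpoints of the subject's closest-ROI-pair bundle centroids, targets are
#' the centers of mass of the corresponding ROIs, weighted by bundle size.
#' Subjects whose geometry is too degenerate for a rigid fit keep the
#' identity pre-alignment.
#'
#' @param fiberSets list of [FiberSet-class], one per subject (>= 2).
#' @param parc a [Parcellation-class].
#' @param cfg an [emConfig()] list.
#' @param dist optional precomputed [DistanceFields-class].
#' @return list with `group` ([GroupModel-class]), per-subject `assignments`
#'   and `reversed` flags from the pooled initialization.
#' @export
initializeGroup <- function(fiberSets, parc, cfg = emConfig(), dist = NULL) {
  if (length(fiberSets) < 2) stop("groupwise bundling needs >= 2 subjects")
  if (is.null(dist)) dist <- buildDistanceFields(parc)
  centers <- roiCenters(parc)
  preps <- lapply(fiberSets, prepareFibers, cfg = cfg)

  transforms <- vector("list", length(fiberSets))
  for (s in seq_along(fiberSets)) {
    phis <- terminalPhis(preps[[s]]$X, cfg$m, dist)
    init <- tryCatch(initFromPhis(preps[[s]], phis, cfg), error = function(e)
      stop("subject ", fiberSets[[s]]@subjectID, ": ", conditionMessage(e)))
    keys <- names(init$model@centroids)
    src <- NULL; tgt <- NULL; w <- NULL
    for (k in keys) {
      mu <- init$model@centroids[[k]]
      lab <- keyLabels(k)
      nk <- sum(init$assignment == k)
      src <- rbind(src, mu[1, ], mu[nrow(mu), ])
      tgt <- rbind(tgt, centers[lab[1], ], centers[lab[2], ])
      w <- c(w, nk, nk)
    }
    transforms[[s]] <- tryCatch(fitRigid(src, tgt, weights = w),
                                error = function(e) { warning(
      "subject ", fiberSets[[s]]@subjectID,
      ": rigid pre-alignment degenerate, keeping identity"); NULL })
  }

  # classify the rigidly warped fibers and pool the initial centroids
  assignments <- vector("list", length(fiberSets))
  reversedL <- vector("list", length(fiberSets))
  acc <- list(); cnt <- list()
  for (s in seq_along(fiberSets)) {
    Xw <- warpStacked(transforms[[s]], preps[[s]]$X, cfg$m)
    prepW <- list(X = Xw, Xrev = reverseStacked(Xw, cfg$m), m = cfg$m, J = nrow(Xw))
    phis <- terminalPhis(Xw, cfg$m, dist)
    init <- initFromPhis(prepW, phis, cfg)
    assignments[[s]] <- init$assignment
    reversedL[[s]] <- init$reversed
    for (k in unique(init$assignment)) {
      jj <- which(init$assignment == k)
      Xk <- prepW$X[jj, , drop = FALSE]
      rr <- init$reversed[jj]
      if (any(rr)) Xk[rr, ] <- prepW$Xrev[jj[rr], , drop = FALSE]
      if (is.null(acc[[k]])) { acc[[k]] <- colSums(Xk); cnt[[k]] <- length(jj) }
      else { acc[[k]] <- acc[[k]] + colSums(Xk); cnt[[k]] <- cnt[[k]] + length(jj) }
    }
  }
  keys <- orderKeys(names(acc))
  cents <- setNames(lapply(keys, function(k) unflatten(acc[[k]] / cnt[[k]])), keys)
  model <- BundleModel(cents, cfg$sigmaBundle, cfg$sigmaRoi)
  group <- new("GroupModel", model = model, transforms = transforms,
               subjectIDs = vapply(fiberSets, subjectID, character(1)))
  list(group = group, assignments = assignments, reversed = reversedL)
}

#' Groupwise E-step
#'
#' Warps each subject's fibers into the common space with its current
#' transform and computes fiber-to-bundle responsibilities against the common
#' centroids, with the same gated log-space machinery as [eStep()]; terminal
#' distances are evaluated at the warped terminals.
#'
#' @param fiberSets list of [FiberSet-class].
#' @param group a [GroupModel-class].
#' @param dist [DistanceFields-class] of the common-space parcellation.
#' @param cfg an [emConfig()] list.
#' @return list of [Membership-class], one per subject.
#' @export
groupEStep <- function(fiberSets, group, dist, cfg = emConfig()) {
  lapply(seq_along(fiberSets), function(s) {
    prep <- prepareFibers(fiberSets[[s]], cfg)
    Xw <- warpStacked(group@transforms[[s]], prep$X, cfg$m)
    prepW <- list(X = Xw, Xrev = reverseStacked(Xw, cfg$m), m = cfg$m, J = prep$J)
    phis <- terminalPhis(Xw, cfg$m, dist)
    bl <- bundleLogLik(prepW, phis, group@model, cfg)
    nm <- normalizeMemberships(bl$ll)
    new("Membership", values = nm$values, keys = names(group@model@centroids),
        reversed = bl$reversed, unassigned = nm$unassigned)
  })
}

# Internal: stacked warped fiber matrices per subject (avoids re-resampling).
warpAllStacked <- function(preps, transforms, m) {
  lapply(seq_along(preps), function(s) warpStacked(transforms[[s]], preps[[s]]$X, m))
}

#' Update common centroids from all subjects
#'
#' Responsibility-weighted point-wise mean of the warped fibers of all
#' subjects, normalized per bundle:
#' \deqn{\mu_{k,i} = \sum_s \sum_j m^s_{j,k}\, T^s(x^s_{j,i}) \big/
#'   \sum_s \sum_j m^s_{j,k}.}
#' Zero-mass bundles are dropped. `denominator = "pooled_over_k"` instead
#' divides by the mass summed over all bundles (a literal reading of an
#' alternative normalization; not a mean, retained only for comparison).
#'
#' @param fiberSets list of [FiberSet-class].
#' @param memberships list of [Membership-class] from [groupEStep()].
#' @param transforms list of per-subject transforms (NULL = identity).
#' @param cfg an [emConfig()] list.
#' @param denominator `"bundle"` (default) or `"pooled_over_k"`.
#' @return named list of m x 3 centroid matrices.
#' @export
updateCommonCentroids <- function(fiberSets, memberships, transforms,
                                  cfg = emConfig(),
                                  denominator = c("bundle", "pooled_over_k")) {
  denominator <- match.arg(denominator)
  preps <- lapply(fiberSets, prepareFibers, cfg = cfg)
  Xws <- warpAllStacked(preps, transforms, cfg$m)
  keys <- memberships[[1]]@keys
  num <- matrix(0, length(keys), 3 * cfg$m)
  den <- numeric(length(keys))
  for (s in seq_along(fiberSets)) {
    Xw <- Xws[[s]]
    XwRev <- reverseStacked(Xw, cfg$m)
    V <- memberships[[s]]@values
    Rv <- memberships[[s]]@reversed
    for (k in seq_along(keys)) {
      sel <- which(V[, k] > 0)
      if (!length(sel)) next
      Xk <- Xw[sel, , drop = FALSE]
      rr <- Rv[sel, k]
      if (any(rr)) Xk[rr, ] <- XwRev[sel[rr], , drop = FALSE]
      num[k, ] <- num[k, ] + colSums(Xk * V[sel, k])
      den[k] <- den[k] + sum(V[sel, k])
    }
  }
  keep <- den > 1e-12
  div <- if (denominator == "bundle") den else rep(sum(den), length(den))
  cents <- lapply(which(keep), function(k) unflatten(num[k, ] / div[k]))
  names(cents) <- keys[keep]
  cents
}

#' Per-subject bundle centroids in native space
#'
#' For each subject and bundle, the responsibility-weighted mean of that
#' subject's own (native-space, orientation-normalized) fibers, together with
#' the bundle's responsibility mass. These are the moving point sets that the
#' transform update aligns to the common centroids. A bundle counts as
#' present in a subject only when its responsibility mass reaches `minMass`
#' (default half a fiber): below that the weighted mean renormalizes
#' responsibility dust from unrelated fibers and is not a centroid estimate.
#' Absent (subject, bundle) pairs are omitted.
#'
#' @inheritParams updateCommonCentroids
#' @param minMass presence threshold on the responsibility mass.
#' @return list (one per subject) of lists with `centroids` (named list of
#'   m x 3 matrices) and `masses` (named numeric).
#' @export
subjectCentroids <- function(fiberSets, memberships, cfg = emConfig(),
                             minMass = 0.5) {
  lapply(seq_along(fiberSets), function(s) {
    prep <- prepareFibers(fiberSets[[s]], cfg)
    up <- mStepInternal(prep, memberships[[s]]@values, memberships[[s]]@reversed,
                        cfg, hard = FALSE)
    keep <- names(up$masses)[up$masses >= minMass]
    list(centroids = up$model@centroids[keep], masses = up$masses[keep])
  })
}

#' Update per-subject transforms by aligning bundle centroids
#'
#' Fits, for each subject, a thin-plate spline from its native-space bundle
#' centroids to the corresponding common centroids, using every 3rd centroid
#' point (indices 1, 4, 7, ... of each curve; `downsample` controls the
#' stride) as control points weighted by bundle mass. Aligning centroids
#' rather than all fibers makes the cost proportional to the bundle count.
#' Subjects with too few correspondences keep their previous transform, with
#' a warning.
#'
#' @param subjCents output of [subjectCentroids()].
#' @param commonCents named list of common centroid matrices.
#' @param cfg an [emConfig()] list.
#' @param previous list of previous transforms (fallback).
#' @param downsample centroid point stride (default 3).
#' @param tpsLambda TPS regularization; NULL = automatic (see [fitTPS()]).
#' @param weighted weight control points by bundle mass (default TRUE).
#' @return list of transforms, one per subject.
#' @export
updateTransforms <- function(subjCents, commonCents, cfg = emConfig(),
                             previous = NULL, downsample = 3L,
                             tpsLambda = NULL, weighted = TRUE) {
  idx <- seq(1L, cfg$m, by = as.integer(downsample))
  lapply(seq_along(subjCents), function(s) {
    sc <- subjCents[[s]]
    keys <- intersect(names(sc$centroids), names(commonCents))
    prev <- if (is.null(previous)) NULL else previous[[s]]
    if (length(keys) < 2) {
      warning("subject ", s, ": too few shared bundles; keeping previous transform")
      return(prev)
    }
    src <- NULL; tgt <- NULL; w <- NULL
    for (k in keys) {
      mus <- sc$centroids[[k]]
      muc <- commonCents[[k]]
      o <- orientFiber(mus, muc)   # cross-space orientation safety
      src <- rbind(src, o$points[idx, , drop = FALSE])
      tgt <- rbind(tgt, muc[idx, , drop = FALSE])
      w <- c(w, rep(sc$masses[[k]], length(idx)))
    }
    tryCatch(
      fitTPS(src, tgt, lambda = tpsLambda, weights = if (weighted) w else NULL),
      error = function(e) {
        warning("subject ", s, ": TPS update failed (", conditionMessage(e),
                "); keeping previous transform")
        prev
      })
  })
}

# Weighted mean of per-subject centroids (optionally warped), oriented to a
# common reference; used by the baseline group methods.
poolSubjectCentroids <- function(subjCents, transforms = NULL, m) {
  keys <- orderKeys(unique(unlist(lapply(subjCents, function(x) names(x$centroids)))))
  cents <- list()
  for (k in keys) {
    num <- 0; den <- 0; ref <- NULL
    for (s in seq_along(subjCents)) {
      mu <- subjCents[[s]]$centroids[[k]]
      if (is.null(mu)) next
      if (!is.null(transforms)) mu <- warpPoints(transforms[[s]], mu)
      if (is.null(ref)) ref <- mu else mu <- orientFiber(mu, ref)$points
      w <- subjCents[[s]]$masses[[k]]
      num <- num + w * mu; den <- den + w
    }
    if (den > 1e-12) cents[[k]] <- num / den
  }
  cents
}

#' Run groupwise bundling
#'
#' Joint estimation of common bundle centroids and per-subject nonrigid
#' (thin-plate-spline) alignment by EM (`method = "groupwise"`): each
#' iteration computes responsibilities of the warped fibers against the
#' common centroids, updates the common centroids with transforms fixed,
#' summarizes each subject by its native-space bundle centroids, and re-fits
#' the per-subject transforms by aligning those to the common centroids.
#' Stops when the total number of hard-assignment changes across subjects is
#' at most `groupChangeThreshold` (default 20 per subject) or after
#' `cfg$maxIterations` iterations.
#'
#' Baseline methods: `"independent"` bundles every subject separately with
#' [runEM()] and applies no alignment; `"posthoc_tps"` does the same and then
#' fits one TPS per subject to map its bundle centroids onto the group means
#' afterwards; `"pooled"` concatenates all subjects' fibers and runs a single
#' [runEM()] in the common space with no per-subject alignment.
#'
#' @param fiberSets list of [FiberSet-class], one per subject.
#' @param parc a [Parcellation-class] (or precomputed
#'   [DistanceFields-class] via `dist`).
#' @param cfg an [emConfig()] list.
#' @param method one of `"groupwise"`, `"independent"`, `"posthoc_tps"`,
#'   `"pooled"`.
#' @param groupChangeThreshold assignment-change threshold summed over
#'   subjects; default `cfg$changeThreshold * S`.
#' @param downsample,tpsLambda,weighted passed to [updateTransforms()].
#' @param dist optional precomputed [DistanceFields-class].
#' @return list with `group` ([GroupModel-class]), `assignments` (list of
#'   per-fiber keys per subject), `memberships`, `subjCents` (per-subject
#'   native centroids + masses), `trace`, `method`, `config`.
#' @export
runGroupEM <- function(fiberSets, parc, cfg = emConfig(),
                       method = c("groupwise", "independent", "posthoc_tps", "pooled"),
                       groupChangeThreshold = NULL, downsample = 3L,
                       tpsLambda = NULL, weighted = TRUE, dist = NULL) {
  method <- match.arg(method)
  if (is.null(dist)) dist <- buildDistanceFields(parc)
  S <- length(fiberSets)
  if (is.null(groupChangeThreshold)) groupChangeThreshold <- cfg$changeThreshold * S
  subjIDs <- vapply(fiberSets, subjectID, character(1))

  if (method %in% c("independent", "posthoc_tps")) {
    runs <- lapply(fiberSets, runEM, parc = dist, cfg = cfg)
    subjCents <- lapply(runs, function(r) {
      mass <- colSums(r$membership@values)
      keep <- names(r$model@centroids)[mass[names(r$model@centroids)] >= 0.5]
      list(centroids = r$model@centroids[keep], masses = mass[keep])
    })
    common <- poolSubjectCentroids(subjCents, transforms = NULL, m = cfg$m)
    transforms <- vector("list", S)
    if (method == "posthoc_tps") {
      transforms <- updateTransforms(subjCents, common, cfg,
                                     downsample = downsample,
                                     tpsLambda = tpsLambda, weighted = weighted)
      common <- poolSubjectCentroids(subjCents, transforms, m = cfg$m)
    }
    group <- new("GroupModel",
                 model = BundleModel(common, cfg$sigmaBundle, cfg$sigmaRoi),
                 transforms = transforms, subjectIDs = subjIDs)
    return(list(group = group,
                assignments = lapply(runs, `[[`, "assignment"),
                memberships = lapply(runs, `[[`, "membership"),
                subjCents = subjCents,
                trace = lapply(runs, `[[`, "trace"),
                method = method, config = cfg))
  }

  if (method == "pooled") {
    allFibers <- do.call(c, lapply(fiberSets, fibers))
    pooledFS <- FiberSet(allFibers, subjectID = "pooled")
    run <- runEM(pooledFS, dist, cfg = cfg)
    sizes <- vapply(fiberSets, nFibers, 1L)
    splitIdx <- rep(seq_len(S), sizes)
    assignments <- split(run$assignment, splitIdx)
    memberships <- lapply(seq_len(S), function(s) {
      rows <- which(splitIdx == s)
      new("Membership", values = run$membership@values[rows, , drop = FALSE],
          keys = run$membership@keys,
          reversed = run$membership@reversed[rows, , drop = FALSE],
          unassigned = run$membership@unassigned[rows])
    })
    subjCents <- subjectCentroids(fiberSets, memberships, cfg)
    group <- new("GroupModel", model = run$model,
                 transforms = vector("list", S), subjectIDs = subjIDs)
    return(list(group = group, assignments = unname(assignments),
                memberships = memberships, subjCents = subjCents,
                trace = run$trace, method = method, config = cfg))
  }

  # full groupwise EM
  init <- initializeGroup(fiberSets, parc, cfg, dist = dist)
  group <- init$group
  assignPrev <- init$assignments
  preps <- lapply(fiberSets, prepareFibers, cfg = cfg)
  trace <- NULL
  memberships <- NULL; subjCents <- NULL
  for (n in seq_len(cfg$maxIterations)) {
    memberships <- lapply(seq_len(S), function(s) {
      Xw <- warpStacked(group@transforms[[s]], preps[[s]]$X, cfg$m)
      prepW <- list(X = Xw, Xrev = reverseStacked(Xw, cfg$m),
                    m = cfg$m, J = preps[[s]]$J)
      phis <- terminalPhis(Xw, cfg$m, dist)
      bl <- bundleLogLik(prepW, phis, group@model, cfg)
      nm <- normalizeMemberships(bl$ll)
      new("Membership", values = nm$values,
          keys = names(group@model@centroids),
          reversed = bl$reversed, unassigned = nm$unassigned)
    })
    assignNow <- lapply(memberships, function(mm)
      hardAssign(mm@values, mm@keys, mm@unassigned))
    changes <- sum(vapply(seq_len(S), function(s) {
      a <- assignNow[[s]]; b <- assignPrev[[s]]
      sum(a != b, na.rm = TRUE) + sum(xor(is.na(a), is.na(b)))
    }, 1))
    common <- updateCommonCentroids(fiberSets, memberships, group@transforms, cfg)
    subjCents <- subjectCentroids(fiberSets, memberships, cfg)
    transforms <- updateTransforms(subjCents, common, cfg,
                                   previous = group@transforms,
                                   downsample = downsample,
                                   tpsLambda = tpsLambda, weighted = weighted)
    group <- new("GroupModel",
                 model = BundleModel(common, cfg$sigmaBundle, cfg$sigmaRoi),
                 transforms = transforms, subjectIDs = subjIDs)
    # Eq-12-style objective under the updated centroids and transforms
    obj <- 0
    for (s in seq_len(S)) {
      Xw <- warpStacked(group@transforms[[s]], preps[[s]]$X, cfg$m)
      prepW <- list(X = Xw, Xrev = reverseStacked(Xw, cfg$m),
                    m = cfg$m, J = preps[[s]]$J)
      phis <- terminalPhis(Xw, cfg$m, dist)
      bl2 <- bundleLogLik(prepW, phis, group@model, cfg)
      keep <- match(names(group@model@centroids), memberships[[s]]@keys)
      V <- memberships[[s]]@values[, keep, drop = FALSE]
      # entries gated only under the *updated* transforms carry -Inf here;
      # they are outside the objective both blocks optimized, so skip them
      q <- V * bl2$ll
      obj <- obj + sum(q[V > 0 & is.finite(bl2$ll)])
    }
    trace <- rbind(trace, data.frame(iteration = n, changes = changes,
                                     objective = obj))
    assignPrev <- assignNow
    if (changes <= groupChangeThreshold) break
  }
  # the in-loop centroid update fixes transforms at their previous value;
  # finish with one centroid update under the final transforms so the
  # returned (centroids, transforms) pair is mutually consistent
  common <- updateCommonCentroids(fiberSets, memberships, group@transforms, cfg)
  group <- new("GroupModel",
               model = BundleModel(common, cfg$sigmaBundle, cfg$sigmaRoi),
               transforms = group@transforms, subjectIDs = subjIDs)
  list(group = group, assignments = assignPrev, memberships = memberships,
       subjCents = subjCents, trace = trace, method = method, config = cfg)
}
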