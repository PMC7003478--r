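#' Synthetic ball-ROI parcellation
#'
#' Generates L disjoint ball-shaped ROIs at Poisson-disk-sampled centers
#' (pairwise center distance > 2 * radius + 2 voxels) on a cubic grid,
#' standing in for an atlas parcellation. Deterministic given `seed`.
#'
#' @param grid grid side length in voxels (cubic grid) or length-3 vector.
#' @param L number of ROIs.
#' @param roiRadius ball radius in voxels.
#' @param seed integer seed.
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(grid = 48L, L = 12L, roiRadius = 4, seed = 1L) {
  dims <- if (length(grid) == 1) rep(as.integer(grid), 3) else as.integer(grid)
  margin <- roiRadius + 1
  minSep <- 2 * roiRadius + 2
  withSeed(seed, {
    centers <- NULL
    for (attempt in 1:25) {
      centers <- matrix(NA_real_, 0, 3)
      tries <- 0
      while (nrow(centers) < L && tries < 4000) {
        tries <- tries + 1
        cand <- runif(3, margin, dims - 1 - margin)
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > minSep)
          centers <- rbind(centers, cand)
      }
      if (nrow(centers) == L) break
      centers <- NULL
    }
    if (is.null(centers))
      stop("could not pack ", L, " ROIs of radius ", roiRadius,
           " into the grid; reduce L or roiRadius")
    lab <- array(0L, dims)
    rg <- ceiling(roiRadius)
    for (l in seq_len(L)) {
      c0 <- centers[l, ]
      lo <- pmax(floor(c0 - rg), 0); hi <- pmin(ceiling(c0 + rg), dims - 1)
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      gr <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      inside <- sqrt(rowSums(sweep(gr, 2, c0)^2)) <= roiRadius
      lab[gr[inside, , drop = FALSE] + 1L] <- l
    }
    p <- Parcellation(lab)
    attr(p, "centers") <- centers
    p
  })
}

#' Synthetic ground-truth bundle centroids
#'
#' Draws K distinct ROI pairs and builds a smooth centroid curve for each: a
#' quadratic Bezier from one ROI center to the other whose midpoint is bowed
#' sideways by a random perpendicular offset (5-20% of the chord), resampled
#' to m equally spaced points. Endpoints therefore lie inside their ROIs.
#'
#' @param parc a [Parcellation-class] from [makeParcellation()].
#' @param K number of bundles (<= L(L-1)/2).
#' @param m points per centroid.
#' @param seed integer seed.
#' @return named list of m x 3 centroid matrices keyed by "l1-l2".
#' @export
makeBundles <- function(parc, K = 10L, m = 20L, seed = 1L) {
  centers <- attr(parc, "centers")
  if (is.null(centers)) centers <- roiCenters(parc)
  L <- parc@L
  if (K > L * (L - 1) / 2) stop("K exceeds the number of ROI pairs")
  withSeed(seed, {
    pairs <- t(utils::combn(L, 2))
    sel <- pairs[sample.int(nrow(pairs), K), , drop = FALSE]
    cents <- list()
    for (i in seq_len(K)) {
      c1 <- centers[sel[i, 1], ]; c2 <- centers[sel[i, 2], ]
      chord <- c2 - c1
      d <- sqrt(sum(chord^2))
      u <- rnorm(3)
      u <- u - sum(u * chord) / d^2 * chord        # perpendicular component
      u <- u / sqrt(sum(u^2))
      bow <- runif(1, 0.05, 0.2) * d
      cm <- (c1 + c2) / 2 + bow * u
      tt <- seq(0, 1, length.out = 200)
      bez <- outer((1 - tt)^2, c1) + outer(2 * tt * (1 - tt), cm) + outer(tt^2, c2)
      cents[[bundleKey(sel[i, 1], sel[i, 2])]] <- resampleFiber(bez, m)
    }
    cents[orderKeys(names(cents))]
  })
}

#' Sample noisy fibers around ground-truth centroids
#'
#' Emulates the generative model the bundling algorithm assumes: each fiber
#' is its bundle centroid plus i.i.d. isotropic Gaussian noise at every
#' point, with additional isotropic jitter at the two terminals (mimicking
#' the accumulation of tracking error at fiber endpoints), and random
#' point-order reversal with probability 1/2 (streamline files carry no
#' canonical direction).
#'
#' @param cents named list of centroid matrices (see [makeBundles()]).
#' @param nPerBundle fibers per bundle.
#' @param pointNoise per-point noise standard deviation (voxels).
#' @param terminalJitter additional terminal jitter standard deviation.
#' @param seed integer seed.
#' @param subjectID subject label for the resulting [FiberSet-class].
#' @return list with `fiberSet` ([FiberSet-class]), `trueKeys` (character,
#'   per fiber), and `trueReversed` (logical, per fiber).
#' @export
sampleFibers <- function(cents, nPerBundle = 50L, pointNoise = 1,
                         terminalJitter = 1, seed = 1L, subjectID = "subject") {
  if (pointNoise < 0 || terminalJitter < 0) stop("noise must be >= 0")
  withSeed(seed, {
    fibersL <- list(); keys <- character(); revs <- logical()
    m <- nrow(cents[[1]])
    for (k in names(cents)) {
      mu <- cents[[k]]
      for (i in seq_len(nPerBundle)) {
        f <- mu + matrix(rnorm(3 * m, sd = pointNoise), m, 3)
        f[1, ] <- f[1, ] + rnorm(3, sd = terminalJitter)
        f[m, ] <- f[m, ] + rnorm(3, sd = terminalJitter)
        rv <- runif(1) < 0.5
        if (rv) f <- f[m:1, , drop = FALSE]
        fibersL[[length(fibersL) + 1L]] <- f
        keys <- c(keys, k); revs <- c(revs, rv)
      }
    }
    list(fiberSet = FiberSet(fibersL, subjectID = subjectID),
         trueKeys = keys, trueReversed = revs)
  })
}

#' Default single-subject phantom
#'
#' Builds a complete ground-truthed dataset: a ball-ROI parcellation, K true
#' bundle centroids, and one noisy fiber set. Sub-seeds are derived from
#' `seed` per component, so e.g. changing `nPerBundle` does not perturb the
#' parcellation geometry. Defaults: 48^3 grid, L = 12 ROIs of radius 4,
#' K = 10 bundles, 50 fibers per bundle, point noise 1.0 voxel, terminal
#' jitter 1.0 voxel, m = 20 — sized so whole test suites run in minutes.
#'
#' @param seed master integer seed.
#' @param grid,L,roiRadius see [makeParcellation()].
#' @param K,m see [makeBundles()].
#' @param nPerBundle,pointNoise,terminalJitter see [sampleFibers()].
#' @return list with `parc`, `cents`, `fiberSet`, `trueKeys`,
#'   `trueReversed`, and the generator `params`.
#' @export
makePhantom <- function(seed = 1L, grid = 48L, L = 12L, roiRadius = 4,
                        K = 10L, m = 20L, nPerBundle = 50L,
                        pointNoise = 1, terminalJitter = 1) {
  parc <- makeParcellation(grid, L, roiRadius, seed = deriveSeed(seed, 1))
  cents <- makeBundles(parc, K, m, seed = deriveSeed(seed, 2))
  smp <- sampleFibers(cents, nPerBundle, pointNoise, terminalJitter,
                      seed = deriveSeed(seed, 3))
  list(parc = parc, cents = cents, fiberSet = smp$fiberSet,
       trueKeys = smp$trueKeys, trueReversed = smp$trueReversed,
       params = list(seed = seed, grid = grid, L = L, roiRadius = roiRadius,
                     K = K, m = m, nPerBundle = nPerBundle,
                     pointNoise = pointNoise, terminalJitter = terminalJitter))
}

# Random smooth TPS warp of a given typical displacement magnitude over the
# grid; rejects folding warps (negative Jacobian at sampled points).
randomSmoothWarp <- function(dims, magnitude, seed) {
  withSeed(seed, {
    gr <- lapply(dims, function(d) seq(2, d - 3, length.out = 3))
    ctrl <- as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]]))
    dimnames(ctrl) <- NULL
    for (try in 1:20) {
      disp <- matrix(rnorm(nrow(ctrl) * 3), ncol = 3)
      disp <- disp / sqrt(rowSums(disp^2)) * magnitude
      w <- fitTPS(ctrl, ctrl + disp, lambda = 0)
      if (magnitude == 0) return(w)
      # sample the Jacobian determinant on a coarse grid
      qs <- as.matrix(expand.grid(seq(0, dims[1] - 1, length.out = 5),
                                  seq(0, dims[2] - 1, length.out = 5),
                                  seq(0, dims[3] - 1, length.out = 5)))
      h <- 0.5; ok <- TRUE
      f0 <- warpPoints(w, qs)
      J1 <- (warpPoints(w, sweep(qs, 2, c(h, 0, 0), "+")) - f0) / h
      J2 <- (warpPoints(w, sweep(qs, 2, c(0, h, 0), "+")) - f0) / h
      J3 <- (warpPoints(w, sweep(qs, 2, c(0, 0, h), "+")) - f0) / h
      for (q in seq_len(nrow(qs))) {
        if (det(cbind(J1[q, ], J2[q, ], J3[q, ])) <= 0) { ok <- FALSE; break }
      }
      if (ok) return(w)
    }
    stop("could not sample a fold-free warp; reduce magnitude")
  })
}

#' Multi-subject phantom with injected misregistration
#'
#' For each of S subjects, samples a fresh fiber set from the phantom's true
#' centroids and applies an independent smooth thin-plate-spline warp with
#' control displacements of the given magnitude (voxels), emulating residual
#' nonrigid misregistration after template mapping. The applied warps are
#' returned as ground truth; a perfect groupwise fit recovers their
#' inverses. Warps with non-positive sampled Jacobians are rejected and
#' redrawn.
#'
#' @param phantom output of [makePhantom()].
#' @param S number of subjects (>= 2).
#' @param warpMagnitude control-point displacement magnitude in voxels
#'   (should stay below the ROI radius so labels remain meaningful).
#' @param seed integer seed.
#' @return list with `fiberSets` (warped, one per subject), `trueWarps`
#'   (list of [TPSTransform-class]), `trueKeys` (per subject), and the
#'   unwarped `cleanFiberSets`.
#' @export
makeGroup <- function(phantom, S = 5L, warpMagnitude = 2, seed = 1L) {
  if (warpMagnitude >= phantom$params$roiRadius)
    warning("warp magnitude >= ROI radius; labels may lose meaning")
  dims <- dim(phantom$parc@labels)
  fiberSets <- vector("list", S); cleans <- vector("list", S)
  warps <- vector("list", S); keys <- vector("list", S)
  for (s in seq_len(S)) {
    smp <- sampleFibers(phantom$cents, phantom$params$nPerBundle,
                        phantom$params$pointNoise, phantom$params$terminalJitter,
                        seed = deriveSeed(seed, 100 + s),
                        subjectID = sprintf("sub-%02d", s))
    w <- randomSmoothWarp(dims, warpMagnitude, seed = deriveSeed(seed, 200 + s))
    warped <- lapply(fibers(smp$fiberSet), function(f)
      if (warpMagnitude == 0) f else warpPoints(w, f))
    fiberSets[[s]] <- FiberSet(warped, subjectID = sprintf("sub-%02d", s))
    cleans[[s]] <- smp$fiberSet
    warps[[s]] <- w
    keys[[s]] <- smp$trueKeys
  }
  list(fiberSets = fiberSets, trueWarps = warps, trueKeys = keys,
       cleanFiberSets = cleans)
}
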