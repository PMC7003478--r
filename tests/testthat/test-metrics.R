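straightFiber <- function(from, to, m = 20) resampleFiber(rbind(from, to), m)

test_that("MIV is the mean fiber-to-centroid distance", {
  mu <- straightFiber(c(0, 0, 0), c(10, 0, 0))
  cents <- list("1-2" = mu)
  # fibers identical to centroid: 0
  fs <- FiberSet(list(mu, mu[20:1, ]))
  expect_equal(as.numeric(meanInbundleVariation(fs, c("1-2", "1-2"), cents)), 0)
  # constant offsets 1 and 3: mean 2
  fs2 <- FiberSet(list(sweep(mu, 2, c(0, 1, 0), "+"),
                       sweep(mu, 2, c(0, -3, 0), "+")))
  expect_equal(as.numeric(meanInbundleVariation(fs2, c("1-2", "1-2"), cents)), 2)
  # unassigned fibers excluded and counted
  miv <- meanInbundleVariation(fs2, c("1-2", NA), cents)
  expect_equal(as.numeric(miv), 1)
  expect_equal(attr(miv, "nExcluded"), 1L)
})

test_that("MIV on a random phantom equals direct recomputation", {
  ph <- cachedPhantom(1)
  dist <- cachedDist(ph$parc, "ph1")
  res <- runEM(ph$fiberSet, dist, emConfig())
  miv <- meanInbundleVariation(ph$fiberSet, res$assignment, res$model)
  fl <- lapply(fibers(ph$fiberSet), parcbundle:::ensurePoints, m = 20)
  dsum <- 0; n <- 0
  for (j in seq_along(fl)) {
    if (is.na(res$assignment[j])) next
    mu <- res$model@centroids[[res$assignment[j]]]
    f <- fl[[j]]
    if (sum((f[20:1, ] - mu)^2) < sum((f - mu)^2)) f <- f[20:1, ]
    dsum <- dsum + mean(sqrt(rowSums((f - mu)^2)))
    n <- n + 1
  }
  expect_equal(as.numeric(miv), dsum / n)
})

test_that("MED sums winning terminal distances and averages over fibers", {
  parc <- tinyParcellation()
  dist <- cachedDist(parc, "tiny")
  # terminals exactly inside the ROIs: 0
  f <- straightFiber(c(6, 12, 12), c(18, 12, 12))
  fs <- FiberSet(list(f))
  expect_equal(as.numeric(meanEndToRoiDistance(fs, "1-2", dist)), 0)
  # known distances 1 and 2 outside the ball surfaces along the axis
  g <- straightFiber(c(6, 12, 12 + 4), c(18, 12, 12 + 5))
  phi1 <- queryDistance(dist, g[1, ], 1)
  phi2 <- queryDistance(dist, g[20, ], 2)
  expect_equal(as.numeric(meanEndToRoiDistance(FiberSet(list(g)), "1-2", dist)),
               phi1 + phi2)
  expect_equal(phi1 + phi2, 3)
  # swapped fiber: winning correspondence makes MED orientation-free
  expect_equal(as.numeric(meanEndToRoiDistance(FiberSet(list(g[20:1, ])), "1-2", dist)),
               phi1 + phi2)
})

test_that("MED on a random phantom equals direct recomputation", {
  ph <- cachedPhantom(1)
  dist <- cachedDist(ph$parc, "ph1")
  res <- runEM(ph$fiberSet, dist, emConfig())
  med <- meanEndToRoiDistance(ph$fiberSet, res$assignment, dist)
  tot <- 0; n <- 0
  for (j in seq_along(res$assignment)) {
    if (is.na(res$assignment[j])) next
    f <- fibers(ph$fiberSet)[[j]]
    lab <- keyLabels(res$assignment[j])
    r1 <- f[1, ]; r2 <- f[nrow(f), ]
    dA <- c(queryDistance(dist, r1, lab[1]), queryDistance(dist, r2, lab[2]))
    dB <- c(queryDistance(dist, r1, lab[2]), queryDistance(dist, r2, lab[1]))
    tot <- tot + if (sum(dB^2) < sum(dA^2)) sum(dB) else sum(dA)
    n <- n + 1
  }
  expect_equal(as.numeric(med), tot / n)
})

test_that("MBCD averages centroid differences over present pairs", {
  mu <- straightFiber(c(0, 0, 0), c(10, 0, 0))
  common <- list("1-2" = mu)
  subj <- list(list("1-2" = sweep(mu, 2, c(0, 1, 0), "+")),
               list("1-2" = sweep(mu, 2, c(0, -3, 0), "+")))
  expect_equal(meanBundleCentroidDifference(subj, common), 2)
  # equal centroids: 0
  expect_equal(meanBundleCentroidDifference(list(list("1-2" = mu)), common), 0)
  # missing pairs contribute nothing
  subj2 <- list(list("1-2" = sweep(mu, 2, c(0, 2, 0), "+")), list())
  expect_equal(meanBundleCentroidDifference(subj2, common), 2)
  expect_error(meanBundleCentroidDifference(list(list()), common), "no shared")
})

test_that("GMIV reduces to MIV for one subject and identity transforms", {
  ph <- cachedPhantom(1)
  dist <- cachedDist(ph$parc, "ph1")
  res <- runEM(ph$fiberSet, dist, emConfig())
  miv <- meanInbundleVariation(ph$fiberSet, res$assignment, res$model)
  gmiv <- groupwiseMIV(list(ph$fiberSet), list(res$assignment), res$model)
  expect_equal(as.numeric(gmiv), as.numeric(miv))
})

test_that("GMIV on a random group equals direct recomputation", {
  ph <- makePhantom(seed = 90, grid = 36, L = 6, roiRadius = 3.5, K = 3,
                    nPerBundle = 6, pointNoise = 0.5, terminalJitter = 0.5)
  grp <- makeGroup(ph, S = 2, warpMagnitude = 1, seed = 90)
  dist <- buildDistanceFields(ph$parc)
  res <- runGroupEM(grp$fiberSets, ph$parc, emConfig(), dist = dist)
  gmiv <- groupwiseMIV(grp$fiberSets, res$assignments,
                       res$group@model, res$group@transforms)
  tot <- 0; n <- 0
  for (s in 1:2) {
    fl <- lapply(fibers(grp$fiberSets[[s]]), parcbundle:::ensurePoints, m = 20)
    for (j in seq_along(fl)) {
      k <- res$assignments[[s]][j]
      if (is.na(k)) next
      mu <- res$group@model@centroids[[k]]
      f <- warpPoints(res$group@transforms[[s]], fl[[j]])
      if (sum((f[20:1, ] - mu)^2) < sum((f - mu)^2)) f <- f[20:1, ]
      tot <- tot + mean(sqrt(rowSums((f - mu)^2)))
      n <- n + 1
    }
  }
  expect_equal(as.numeric(gmiv), tot / n)
})

test_that("metrics are invariant to fiber order and key enumeration order", {
  ph <- cachedPhantom(1)
  dist <- cachedDist(ph$parc, "ph1")
  res <- runEM(ph$fiberSet, dist, emConfig())
  perm <- sample(seq_along(res$assignment))
  fsPerm <- FiberSet(fibers(ph$fiberSet)[perm])
  mivPerm <- meanInbundleVariation(fsPerm, res$assignment[perm], res$model)
  expect_equal(as.numeric(mivPerm),
               as.numeric(meanInbundleVariation(ph$fiberSet, res$assignment, res$model)))
  centsShuffled <- res$model@centroids[rev(names(res$model@centroids))]
  expect_equal(as.numeric(meanInbundleVariation(ph$fiberSet, res$assignment, centsShuffled)),
               as.numeric(meanInbundleVariation(ph$fiberSet, res$assignment, res$model)))
})

test_that("consistency pruning applies the 2.5-voxel rule with <= retention", {
  mu <- straightFiber(c(0, 0, 0), c(10, 0, 0))
  common <- list("1-2" = mu, "1-3" = mu, "2-3" = mu)
  shift <- function(d) sweep(mu, 2, c(0, d, 0), "+")
  subj <- list(
    list("1-2" = mu, "1-3" = shift(3), "2-3" = shift(2.5)),
    list("1-2" = mu, "1-3" = shift(3), "2-3" = shift(2.5)))
  kept <- pruneInconsistentBundles(subj, common, threshold = 2.5)
  expect_identical(as.character(kept), c("1-2", "2-3"))   # exactly 2.5 retained
  expect_equal(attr(kept, "discarded")[["1-3"]], 3)
  # bundles absent from a subject are discarded
  subj2 <- list(list("1-2" = mu), list("1-2" = mu, "1-3" = mu))
  kept2 <- pruneInconsistentBundles(subj2, common[1:2], threshold = 2.5)
  expect_identical(as.character(kept2), "1-2")
})
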