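# A tiny deterministic setup used by several blocks: two ball ROIs plus two
# more, four bundles of fibers along known centroids.
smallInstance <- function(seed = 50, nPerBundle = 8, pointNoise = 0.4,
                          terminalJitter = 0.4) {
  ph <- makePhantom(seed = seed, grid = 36, L = 6, roiRadius = 3.5, K = 4,
                    nPerBundle = nPerBundle, pointNoise = pointNoise,
                    terminalJitter = terminalJitter)
  ph$dist <- buildDistanceFields(ph$parc)
  ph
}

test_that("initialization averages oriented member fibers per closest pair", {
  parc <- tinyParcellation()
  dist <- cachedDist(parc, "tiny")
  mu <- resampleFiber(rbind(c(6, 12, 12), c(18, 12, 12)), 20)
  # identical fibers: centroid equals the fiber
  fs <- FiberSet(list(mu, mu[20:1, ], mu))
  init <- initializeModel(fs, dist, emConfig())
  expect_identical(names(init$model@centroids), "1-2")
  expect_equal(init$model@centroids[["1-2"]], mu)
  # mirror offsets: centroid on the midline
  off <- c(0, 2, 0)
  fs2 <- FiberSet(list(sweep(mu, 2, off, "+"), sweep(mu, 2, -off, "+")))
  init2 <- initializeModel(fs2, dist, emConfig())
  expect_equal(init2$model@centroids[["1-2"]], mu)
})

test_that("initial centroids equal brute-force oriented per-point means", {
  ph <- smallInstance()
  cfg <- emConfig()
  init <- initializeModel(ph$fiberSet, ph$dist, cfg)
  fl <- lapply(fibers(ph$fiberSet), parcbundle:::ensurePoints, m = 20)
  # exhaustive recomputation: closest pair by label scan, orientation by the
  # winning terminal pairing, plain mean
  keys <- character(length(fl)); oriented <- vector("list", length(fl))
  for (j in seq_along(fl)) {
    f <- fl[[j]]
    pair <- closestRoiPair(ph$dist, f[1, ], f[20, ])
    keys[j] <- bundleKey(pair[1], pair[2])
    tp <- terminalPairLogLikelihood(ph$dist, f[1, ], f[20, ], pair[1], pair[2], cfg$sigmaRoi)
    oriented[[j]] <- if (tp$swapped) f[20:1, ] else f
  }
  expect_identical(init$assignment, keys)
  for (k in names(init$model@centroids)) {
    jj <- which(keys == k)
    mu <- Reduce(`+`, oriented[jj]) / length(jj)
    expect_equal(init$model@centroids[[k]], mu)
  }
})

test_that("gated sparse E-step matches a dense brute-force evaluation", {
  ph <- smallInstance(seed = 51, nPerBundle = 8)  # 32 fibers, 4 bundles
  cfg <- emConfig()
  init <- initializeModel(ph$fiberSet, ph$dist, cfg)
  mem <- eStep(ph$fiberSet, init$model, ph$dist, cfg)
  keys <- bundleKeys(mem)
  fl <- lapply(fibers(ph$fiberSet), parcbundle:::ensurePoints, m = 20)
  gate <- cfg$gateMultiplier * cfg$sigmaRoi
  for (j in seq_along(fl)) {
    f <- fl[[j]]
    # dense oracle: joint likelihood over all bundles, softmax normalization
    ll <- vapply(keys, function(k)
      jointLogLikelihood(f, k, init$model, ph$dist)$logLik, 1)
    dense <- exp(ll - max(ll)); dense <- dense / sum(dense)
    # is any bundle gated for this fiber?
    gated <- vapply(keys, function(k) {
      lab <- keyLabels(k)
      p1 <- queryDistance(ph$dist, f[1, ], lab[1]); p2 <- queryDistance(ph$dist, f[20, ], lab[2])
      q1 <- queryDistance(ph$dist, f[1, ], lab[2]); q2 <- queryDistance(ph$dist, f[20, ], lab[1])
      !((p1 <= gate && p2 <= gate) || (q1 <= gate && q2 <= gate))
    }, TRUE)
    if (!any(gated)) {
      expect_equal(unname(membershipValues(mem)[j, ]), unname(dense),
                   tolerance = 1e-10)
    } else {
      expect_true(all(membershipValues(mem)[j, gated] == 0))
    }
  }
  rs <- rowSums(membershipValues(mem))
  expect_true(all(abs(rs[!mem@unassigned] - 1) < 1e-9))
})

test_that("single-bundle models give membership one and symmetric ties 0.5", {
  parc <- tinyParcellation()
  dist <- cachedDist(parc, "tiny")
  mu <- resampleFiber(rbind(c(6, 12, 12), c(18, 12, 12)), 20)
  model <- BundleModel(list("1-2" = mu), 2, 2)
  set.seed(61)
  fs <- FiberSet(lapply(1:5, function(i) mu + matrix(rnorm(60, sd = 0.3), 20, 3)))
  mem <- eStep(fs, model, dist, emConfig())
  expect_equal(unname(membershipValues(mem)[, 1]), rep(1, 5))

  # two mirror-image bundles, fiber exactly on the midline: 0.5 / 0.5
  muA <- sweep(mu, 2, c(0, 1.5, 0), "+")
  muB <- sweep(mu, 2, c(0, -1.5, 0), "+")
  model2 <- BundleModel(list("1-2" = muA, "1-3" = muB), 2, 2)
  # give both keys valid gates by using clustering mode (no ROI 3 needed)
  mem2 <- eStep(FiberSet(list(mu)), model2, dist,
                emConfig(mode = "clustering_only"))
  expect_equal(unname(membershipValues(mem2)[1, ]), c(0.5, 0.5))
})

test_that("M-step computes weighted oriented means and drops empty bundles", {
  parc <- tinyParcellation()
  dist <- cachedDist(parc, "tiny")
  mu <- resampleFiber(rbind(c(6, 12, 12), c(18, 12, 12)), 20)
  f1 <- sweep(mu, 2, c(0, 1, 0), "+")
  f2 <- sweep(mu, 2, c(0, -1, 0), "+")[20:1, ]   # stored reversed
  fs <- FiberSet(list(f1, f2))
  vals <- matrix(c(0.25, 0.75, 0.75, 0.25), 2, 2,
                 dimnames = list(NULL, c("1-2", "1-3")))
  rev <- matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2)
  mem <- new("Membership", values = vals, keys = c("1-2", "1-3"),
             reversed = rev, unassigned = c(FALSE, FALSE))
  up <- mStep(fs, mem, emConfig())
  manual <- 0.25 * f1 + 0.75 * f2[20:1, ]
  expect_equal(up@centroids[["1-2"]], manual)
  expect_equal(up@centroids[["1-3"]], 0.75 * f1 + 0.25 * f2[20:1, ])

  # all mass on one fiber: centroid equals that fiber; zero-mass bundle dropped
  vals2 <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(NULL, c("1-2", "1-3")))
  mem2 <- new("Membership", values = vals2, keys = c("1-2", "1-3"),
              reversed = matrix(FALSE, 2, 2), unassigned = c(FALSE, TRUE))
  up2 <- mStep(fs, mem2, emConfig())
  expect_identical(names(up2@centroids), "1-2")
  expect_equal(up2@centroids[["1-2"]], f1)
})

test_that("EM converges quickly on a separable phantom and modes behave", {
  ph <- smallInstance(seed = 52, pointNoise = 0.5, terminalJitter = 0.5)
  cfg <- emConfig(changeThreshold = 0)
  res <- runEM(ph$fiberSet, ph$dist, cfg)
  expect_lte(nrow(res$trace), 3)
  expect_equal(res$trace$changes[nrow(res$trace)], 0)
  expect_equal(ariOf(res$assignment, ph$trueKeys), 1)

  # roi_only returns the initialization for any iteration budget
  r1 <- runEM(ph$fiberSet, ph$dist, emConfig(mode = "roi_only", maxIterations = 1))
  r2 <- runEM(ph$fiberSet, ph$dist, emConfig(mode = "roi_only", maxIterations = 9))
  init <- initializeModel(ph$fiberSet, ph$dist, cfg)
  expect_identical(r1$assignment, init$assignment)
  expect_identical(r2$assignment, init$assignment)
})

test_that("sigmaRoi limits recover labeling-only and clustering-only behavior", {
  # unambiguous phantom: terminals well inside their ROIs
  ph <- smallInstance(seed = 53, pointNoise = 0.3, terminalJitter = 0)
  tiny <- runEM(ph$fiberSet, ph$dist, emConfig(sigmaRoi = 0.01))
  init <- initializeModel(ph$fiberSet, ph$dist, emConfig(sigmaRoi = 0.01))
  expect_identical(tiny$assignment, init$assignment)

  huge <- runEM(ph$fiberSet, ph$dist, emConfig(sigmaRoi = 1e6))
  clus <- runEM(ph$fiberSet, ph$dist, emConfig(mode = "clustering_only"))
  expect_identical(huge$assignment, clus$assignment)
})

test_that("the EM objective is non-decreasing with gating disabled", {
  for (seed in 1:6) {
    ph <- smallInstance(seed = seed, nPerBundle = 6)
    # changeThreshold -1 disables early stopping so several iterations run
    res <- runEM(ph$fiberSet, ph$dist,
                 emConfig(gateMultiplier = Inf, changeThreshold = -1,
                          maxIterations = 6))
    expect_gte(nrow(res$trace), 2)
    expect_true(all(diff(res$trace$objective) > -1e-6))
  }
})

test_that("gating leaves assignments essentially unchanged on tame phantoms", {
  ph <- smallInstance(seed = 54)
  a <- runEM(ph$fiberSet, ph$dist, emConfig())$assignment
  b <- runEM(ph$fiberSet, ph$dist, emConfig(gateMultiplier = Inf))$assignment
  expect_gte(mean(a == b, na.rm = TRUE), 0.99)
})

test_that("hard M-step variant also recovers a clean phantom", {
  ph <- smallInstance(seed = 55, pointNoise = 0.3, terminalJitter = 0.3)
  res <- runEM(ph$fiberSet, ph$dist, emConfig(mStepWeights = "hard"))
  expect_equal(ariOf(res$assignment, ph$trueKeys), 1)
})
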