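#' EM configuration
#'
#' Collects the tunable parameters of the bundling algorithms. Defaults
#' follow the model's working settings: sigmaRoi = sigmaBundle = 2 voxels,
#' m = 20 points per fiber, at most 10 iterations, convergence when at most
#' 20 fibers change assignment between iterations, and a terminal gate at
#' 3 x sigmaRoi.
#'
#' @param sigmaRoi terminal-projection standard deviation (voxels, > 0).
#' @param sigmaBundle bundle curve standard deviation (voxels, > 0).
#' @param m resample point count per fiber (>= 2).
#' @param maxIterations iteration cap (>= 1).
#' @param changeThreshold stop when the number of fibers changing hard
#'   assignment in an iteration is <= this value.
#' @param mode `"constrained"` (full model), `"clustering_only"` (curve term
#'   only, no terminal factor and no gate), or `"roi_only"` (closest-ROI-pair
#'   labeling; no EM refinement).
#' @param gateMultiplier memberships are fixed at zero for bundles where no
#'   terminal pairing places both terminals within `gateMultiplier * sigmaRoi`
#'   of the ROIs (sparsification); `Inf` disables gating.
#' @param mStepWeights `"soft"` (responsibility-weighted centroid update) or
#'   `"hard"` (argmax-assignment means).
#' @param seed optional integer seed recorded in outputs.
#' @return list of class `EMConfig`.
#' @export
emConfig <- function(sigmaRoi = 2, sigmaBundle = 2, m = 20L,
                     maxIterations = 10L, changeThreshold = 20L,
                     mode = c("constrained", "clustering_only", "roi_only"),
                     gateMultiplier = 3, mStepWeights = c("soft", "hard"),
                     seed = NULL) {
  mode <- match.arg(mode)
  mStepWeights <- match.arg(mStepWeights)
  if (sigmaRoi <= 0 || sigmaBundle <= 0) stop("sigma values must be > 0")
  if (m < 2) stop("m must be >= 2")
  if (maxIterations < 1) stop("maxIterations must be >= 1")
  structure(list(sigmaRoi = sigmaRoi, sigmaBundle = sigmaBundle,
                 m = as.integer(m), maxIterations = as.integer(maxIterations),
                 changeThreshold = changeThreshold, mode = mode,
                 gateMultiplier = gateMultiplier, mStepWeights = mStepWeights,
                 seed = seed), class = "EMConfig")
}

# ---- internal vectorized engine ------------------------------------------

# Precompute the per-subject arrays the EM iterates over.
prepareFibers <- function(fiberSet, cfg) {
  fl <- lapply(fibers(fiberSet), ensurePoints, m = cfg$m)
  X <- stackFibers(fl)
  list(fibers = fl, X = X, Xrev = reverseStacked(X, cfg$m),
       m = cfg$m, J = length(fl))
}

# Terminal distances of stored-order fibers to all labels: list(phi1, phi2),
# each J x L. X is the stacked fiber matrix.
terminalPhis <- function(X, m, dist) {
  J <- nrow(X)
  t1 <- X[, 1:3, drop = FALSE]
  t2 <- X[, (3 * m - 2):(3 * m), drop = FALSE]
  list(phi1 = matrix(queryDistanceAll(dist, t1), nrow = J),
       phi2 = matrix(queryDistanceAll(dist, t2), nrow = J))
}

# Joint log-likelihood of every fiber against every model bundle.
# Returns ll (J x K, -Inf where gated) and reversed (J x K logical).
bundleLogLik <- function(prep, phis, model, cfg) {
  keys <- names(model@centroids)
  J <- prep$J; K <- length(keys)
  ll <- matrix(-Inf, J, K, dimnames = list(NULL, keys))
  rev <- matrix(FALSE, J, K, dimnames = list(NULL, keys))
  sb2 <- 2 * model@sigmaBundle^2
  sr2 <- 2 * model@sigmaRoi^2
  shapeConst <- -1.5 * cfg$m * log(pi * sb2)
  termConst <- -3 * log(pi * sr2)
  gate <- cfg$gateMultiplier * model@sigmaRoi
  constrained <- cfg$mode == "constrained"
  for (k in seq_len(K)) {
    lab <- keyLabels(keys[k])
    if (constrained && is.finite(gate)) {
      okA <- phis$phi1[, lab[1]] <= gate & phis$phi2[, lab[2]] <= gate
      okB <- phis$phi1[, lab[2]] <= gate & phis$phi2[, lab[1]] <= gate
      pass <- okA | okB
    } else pass <- rep(TRUE, J)
    if (!any(pass)) next
    mu <- flatten(model@centroids[[keys[k]]])
    dF <- prep$X[pass, , drop = FALSE] - rep(mu, each = sum(pass))
    dR <- prep$Xrev[pass, , drop = FALSE] - rep(mu, each = sum(pass))
    d2F <- rowSums(dF * dF)
    d2R <- rowSums(dR * dR)
    revk <- d2R < d2F
    shape <- shapeConst - pmin(d2F, d2R) / sb2
    if (constrained) {
      # terminal term is orientation-free: max over the two pairings
      sA <- phis$phi1[pass, lab[1]]^2 + phis$phi2[pass, lab[2]]^2
      sB <- phis$phi1[pass, lab[2]]^2 + phis$phi2[pass, lab[1]]^2
      shape <- shape + termConst - pmin(sA, sB) / sr2
    }
    ll[pass, k] <- shape
    rev[pass, k] <- revk
  }
  list(ll = ll, reversed = rev)
}

# Normalize joint log-likelihoods into responsibilities (log-sum-exp).
normalizeMemberships <- function(ll) {
  J <- nrow(ll)
  vals <- matrix(0, J, ncol(ll), dimnames = dimnames(ll))
  unassigned <- logical(J)
  for (j in seq_len(J)) {
    row <- ll[j, ]
    lse <- logSumExp(row)
    if (!is.finite(lse)) { unassigned[j] <- TRUE; next }
    v <- exp(row - lse)
    v[!is.finite(row)] <- 0
    vals[j, ] <- v
  }
  list(values = vals, unassigned = unassigned, logLik = NULL)
}

# Hard assignment: argmax membership, ties -> smaller canonical key
# (columns are kept in canonical key order). NA for unassigned fibers.
hardAssign <- function(values, keys, unassigned) {
  idx <- max.col(values, ties.method = "first")
  out <- keys[idx]
  out[unassigned] <- NA_character_
  out
}

# Canonical ordering of bundle keys: by l1, then l2.
orderKeys <- function(keys) {
  lab <- vapply(keys, function(k) keyLabels(k), integer(2))
  keys[order(lab[1, ], lab[2, ])]
}

# ---- public operations ----------------------------------------------------

#' Initialize the bundle model from closest ROI pairs
#'
#' Every fiber is labeled with the ROI pair its terminals are closest to
#' (see [closestRoiPair()]), oriented so that its first point corresponds to
#' the pair's smaller label (the winning terminal pairing), and each occupied
#' pair's initial centroid is the point-wise mean of its member fibers.
#' Pairs with no members are absent from the model.
#'
#' @param fiberSet a [FiberSet-class].
#' @param dist [DistanceFields-class] of the parcellation.
#' @param cfg an [emConfig()] list.
#' @return list with `model` ([BundleModel-class]), `assignment` (character
#'   vector of keys), and `reversed` (logical per fiber).
#' @export
initializeModel <- function(fiberSet, dist, cfg = emConfig()) {
  prep <- prepareFibers(fiberSet, cfg)
  phis <- terminalPhis(prep$X, cfg$m, dist)
  init <- initFromPhis(prep, phis, cfg)
  init
}

# Core of initializeModel, reusing precomputed arrays.
initFromPhis <- function(prep, phis, cfg) {
  J <- prep$J
  L <- ncol(phis$phi1)
  if (L < 2) stop("need at least 2 labels")
  a1 <- max.col(-phis$phi1, ties.method = "first")
  a2 <- max.col(-phis$phi2, ties.method = "first")
  same <- which(a1 == a2)
  for (j in same) {
    if (phis$phi1[j, a1[j]] > phis$phi2[j, a2[j]]) {
      d <- phis$phi1[j, ]; d[a1[j]] <- Inf; a1[j] <- which.min(d)
    } else {
      d <- phis$phi2[j, ]; d[a2[j]] <- Inf; a2[j] <- which.min(d)
    }
  }
  l1 <- pmin(a1, a2); l2 <- pmax(a1, a2)
  keysJ <- paste0(l1, "-", l2)
  # orientation from the winning terminal pairing (ties keep stored order)
  iA <- cbind(seq_len(J), l1)
  iB <- cbind(seq_len(J), l2)
  sA <- phis$phi1[iA]^2 + phis$phi2[iB]^2
  sB <- phis$phi1[iB]^2 + phis$phi2[iA]^2
  reversed <- sB < sA
  keys <- orderKeys(unique(keysJ))
  cents <- vector("list", length(keys)); names(cents) <- keys
  for (k in keys) {
    jj <- which(keysJ == k)
    Xk <- prep$X[jj, , drop = FALSE]
    rr <- reversed[jj]
    if (any(rr)) Xk[rr, ] <- prep$Xrev[jj[rr], , drop = FALSE]
    cents[[k]] <- unflatten(colMeans(Xk))
  }
  if (length(cents) == 0) stop("empty model: no fiber could be assigned")
  list(model = BundleModel(cents, cfg$sigmaBundle, cfg$sigmaRoi),
       assignment = keysJ, reversed = reversed)
}

#' E-step: fiber-to-bundle responsibilities
#'
#' Computes, for every fiber, the responsibilities of all model bundles as
#' the normalized exponentials of the joint log-likelihoods (log-sum-exp
#' normalization). Bundles for which no terminal pairing places both fiber
#' terminals within `gateMultiplier * sigmaRoi` of the ROI pair are gated to
#' exact zero. In `clustering_only` mode the terminal factor and the gate are
#' dropped. Fibers gated from every bundle are flagged unassigned.
#'
#' @inheritParams initializeModel
#' @param model current [BundleModel-class].
#' @return A [Membership-class] object.
#' @export
eStep <- function(fiberSet, model, dist, cfg = emConfig()) {
  prep <- prepareFibers(fiberSet, cfg)
  phis <- terminalPhis(prep$X, cfg$m, dist)
  bl <- bundleLogLik(prep, phis, model, cfg)
  nm <- normalizeMemberships(bl$ll)
  new("Membership", values = nm$values, keys = names(model@centroids),
      reversed = bl$reversed, unassigned = nm$unassigned)
}

#' M-step: membership-weighted centroid update
#'
#' Each bundle centroid becomes the responsibility-weighted point-wise mean
#' of the orientation-normalized fibers. Bundles whose total responsibility
#' mass falls below 1e-12 are dropped from the model.
#'
#' @inheritParams eStep
#' @param membership a [Membership-class] from [eStep()].
#' @return updated [BundleModel-class].
#' @export
mStep <- function(fiberSet, membership, cfg = emConfig()) {
  prep <- prepareFibers(fiberSet, cfg)
  mStepInternal(prep, membership@values, membership@reversed, cfg)$model
}

mStepInternal <- function(prep, values, reversed, cfg,
                          hard = cfg$mStepWeights == "hard",
                          unassigned = NULL) {
  keys <- colnames(values)
  W <- values
  if (hard) {
    idx <- max.col(values, ties.method = "first")
    W <- matrix(0, nrow(values), ncol(values), dimnames = dimnames(values))
    keepRow <- rowSums(values) > 0
    W[cbind(which(keepRow), idx[keepRow])] <- 1
  }
  cents <- list(); masses <- numeric()
  for (k in seq_along(keys)) {
    w <- W[, k]
    mass <- sum(w)
    if (mass < 1e-12) next
    sel <- which(w > 0)
    Xk <- prep$X[sel, , drop = FALSE]
    rr <- reversed[sel, k]
    if (any(rr)) Xk[rr, ] <- prep$Xrev[sel[rr], , drop = FALSE]
    cents[[keys[k]]] <- unflatten(colSums(Xk * w[sel]) / mass)
    masses[keys[k]] <- mass
  }
  list(model = BundleModel(cents, cfg$sigmaBundle, cfg$sigmaRoi), masses = masses)
}

#' Run single-subject EM bundling
#'
#' Alternates [eStep()] and [mStep()] from the closest-ROI-pair
#' initialization. After each E-step, fibers are hard-assigned to their
#' maximum-membership bundle (ties to the smaller canonical key) and the
#' number of assignment changes is counted; the algorithm stops when that
#' count is at most `changeThreshold` or after `maxIterations` iterations.
#' In `roi_only` mode the initialization is returned unrefined.
#'
#' @param fiberSet a [FiberSet-class].
#' @param parc a [Parcellation-class], or a precomputed
#'   [DistanceFields-class].
#' @param cfg an [emConfig()] list.
#' @return list with elements `model` (final [BundleModel-class]),
#'   `assignment` (character keys, NA = unassigned), `membership`
#'   ([Membership-class]), `reversed` (orientation of each fiber relative to
#'   its assigned centroid), `trace` (data.frame: iteration, changes,
#'   objective, logLik), `unassigned` count, and `config`.
#' @export
runEM <- function(fiberSet, parc, cfg = emConfig()) {
  dist <- if (is(parc, "DistanceFields")) parc else buildDistanceFields(parc)
  prep <- prepareFibers(fiberSet, cfg)
  phis <- terminalPhis(prep$X, cfg$m, dist)
  init <- initFromPhis(prep, phis, cfg)
  keys <- names(init$model@centroids)

  if (cfg$mode == "roi_only") {
    values <- matrix(0, prep$J, length(keys), dimnames = list(NULL, keys))
    values[cbind(seq_len(prep$J), match(init$assignment, keys))] <- 1
    rev <- matrix(FALSE, prep$J, length(keys))
    rev[cbind(seq_len(prep$J), match(init$assignment, keys))] <- init$reversed
    mem <- new("Membership", values = values, keys = keys, reversed = rev,
               unassigned = logical(prep$J))
    return(list(model = init$model, assignment = init$assignment,
                membership = mem, reversed = init$reversed,
                trace = data.frame(iteration = integer(), changes = integer(),
                                   objective = numeric(), logLik = numeric()),
                unassigned = 0L, config = cfg, fiberSet = fiberSet))
  }

  model <- init$model
  assignPrev <- init$assignment
  trace <- NULL
  mem <- NULL
  for (n in seq_len(cfg$maxIterations)) {
    bl <- bundleLogLik(prep, phis, model, cfg)
    nm <- normalizeMemberships(bl$ll)
    keys <- names(model@centroids)
    assignNow <- hardAssign(nm$values, keys, nm$unassigned)
    changes <- sum(assignNow != assignPrev, na.rm = TRUE) +
      sum(xor(is.na(assignNow), is.na(assignPrev)))
    up <- mStepInternal(prep, nm$values, bl$reversed, cfg,
                        hard = cfg$mStepWeights == "hard")
    model <- up$model
    # Eq-8a-style objective: memberships times log-likelihoods under the
    # updated centroids (restricted to the updated model's bundles)
    bl2 <- bundleLogLik(prep, phis, model, cfg)
    keep <- match(names(model@centroids), keys)
    q <- nm$values[, keep, drop = FALSE] * bl2$ll
    obj <- sum(q[nm$values[, keep, drop = FALSE] > 0])
    logLik <- sum(apply(bl$ll, 1, logSumExp)[!nm$unassigned])
    trace <- rbind(trace, data.frame(iteration = n, changes = changes,
                                     objective = obj, logLik = logLik))
    mem <- new("Membership", values = nm$values, keys = keys,
               reversed = bl$reversed, unassigned = nm$unassigned)
    assignPrev <- assignNow
    if (changes <= cfg$changeThreshold) break
  }
  revOut <- rep(FALSE, prep$J)
  ki <- match(assignPrev, bundleKeys(mem))
  ok <- !is.na(ki)
  revOut[ok] <- mem@reversed[cbind(which(ok), ki[ok])]
  list(model = model, assignment = assignPrev, membership = mem,
       reversed = revOut, trace = trace,
       unassigned = sum(is.na(assignPrev)), config = cfg, fiberSet = fiberSet)
}
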