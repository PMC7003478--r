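# Shared fixtures, built in code. Distance fields are memoized per session
# since several files use the same small phantoms.

.fixtureCache <- new.env(parent = emptyenv())

cachedPhantom <- function(seed = 1, ...) {
  key <- paste0("ph-", seed, "-", paste(c(...), collapse = "-"))
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makePhantom(seed = seed, ...)
  .fixtureCache[[key]]
}

cachedDist <- function(parc, key) {
  key <- paste0("dist-", key)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- buildDistanceFields(parc)
  .fixtureCache[[key]]
}

# small two-ball parcellation for cheap unit tests
tinyParcellation <- function(grid = 24L, centers = rbind(c(6, 12, 12), c(18, 12, 12)),
                             radius = 3) {
  lab <- array(0L, rep(grid, 3))
  for (l in seq_len(nrow(centers))) {
    gr <- as.matrix(expand.grid(0:(grid - 1), 0:(grid - 1), 0:(grid - 1)))
    inside <- sqrt(rowSums(sweep(gr, 2, centers[l, ])^2)) <= radius
    lab[gr[inside, , drop = FALSE] + 1L] <- l
  }
  Parcellation(lab)
}

# brute-force distance from points to the nearest voxel center of a label
bruteDistance <- function(parc, points, label) {
  vox <- which(labelArray(parc) == label, arr.ind = TRUE) - 1
  apply(points, 1, function(p) min(sqrt(colSums((t(vox) - p)^2))))
}

# trilinear interpolation of the exact per-voxel EDT, written independently
bruteDistanceTrilinear <- function(parc, p, label) {
  key <- paste0("bruteEDT-", label, "-", paste(dim(labelArray(parc)), collapse = "x"),
                "-", sum(labelArray(parc) == label))
  if (is.null(.fixtureCache[[key]])) {
    dims <- dim(labelArray(parc))
    vox <- which(labelArray(parc) == label, arr.ind = TRUE) - 1
    fld <- array(0, dims)
    gr <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1), 0:(dims[3] - 1)))
    dmin <- apply(gr, 1, function(q) min(sqrt(colSums((t(vox) - q)^2))))
    fld[gr + 1] <- dmin
    .fixtureCache[[key]] <- fld
  }
  fld <- .fixtureCache[[key]]
  dims <- dim(fld)
  p <- pmin(pmax(p, 0), dims - 1)
  i0 <- pmin(floor(p), dims - 2); fr <- p - i0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[1] else 1 - fr[1]) * (if (dy) fr[2] else 1 - fr[2]) *
      (if (dz) fr[3] else 1 - fr[3])
    val <- val + w * fld[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  val
}

ariOf <- function(a, b) {
  skip_if_not_installed("mclust")
  mclust::adjustedRandIndex(a, b)
}
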