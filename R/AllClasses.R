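#' FiberSet: a subject's tractography streamlines in label-grid coordinates
#'
#' Container for one subject's streamlines ("fibers"). Each fiber is an
#' ordered 3-D polyline stored as an n x 3 numeric matrix in continuous,
#' 0-based voxel coordinates of the parcellation grid (the center of the
#' corner voxel is (0,0,0)). All model geometry (sigma values, metrics) is
#' expressed in these voxel units; world-mm coordinates exist only at I/O.
#'
#' @slot fibers list of n_i x 3 numeric matrices, one per fiber, n_i >= 2.
#' @slot affine 4 x 4 matrix mapping 0-based voxel coordinates of the label
#'   grid to world mm (NIfTI sform convention); used only when writing.
#' @slot subjectID single string identifying the subject.
#' @export
setClass("FiberSet", representation(
  fibers = "list", affine = "matrix", subjectID = "character"
))

setValidity("FiberSet", function(object) {
  msg <- character()
  for (i in seq_along(object@fibers)) {
    f <- object@fibers[[i]]
    if (!is.matrix(f) || ncol(f) != 3) { msg <- c(msg, sprintf("fiber %d is not an n x 3 matrix", i)); next }
    if (nrow(f) < 2) msg <- c(msg, sprintf("fiber %d has fewer than 2 points", i))
    if (!all(is.finite(f))) msg <- c(msg, sprintf("fiber %d has non-finite coordinates", i))
  }
  if (!identical(dim(object@affine), c(4L, 4L))) msg <- c(msg, "affine must be 4 x 4")
  else if (!is.finite(determinant(object@affine)$modulus)) msg <- c(msg, "affine must be invertible")
  if (length(object@subjectID) != 1) msg <- c(msg, "subjectID must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a FiberSet
#'
#' @param fibers list of n x 3 numeric matrices (voxel coordinates).
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @param subjectID subject identifier string.
#' @return A [FiberSet-class] object.
#' @export
FiberSet <- function(fibers, affine = diag(4), subjectID = "subject") {
  fibers <- lapply(fibers, function(f) {
    f <- stopIfNot3(f, "fiber")
    dimnames(f) <- NULL
    f
  })
  new("FiberSet", fibers = fibers, affine = affine, subjectID = subjectID)
}

#' Parcellation: integer gray-matter label volume
#'
#' A 3-D integer label volume in which 0 is background and labels 1..L are
#' disjoint gray-matter regions of interest (one label per voxel).
#'
#' @slot labels 3-D integer array of labels.
#' @slot affine 4 x 4 voxel-to-world matrix (0-based voxel convention).
#' @slot L number of labels (maximum label value; individual labels may be
#'   empty in sparse labelings and are rejected at distance-field build).
#' @export
setClass("Parcellation", representation(
  labels = "array", affine = "matrix", L = "integer"
))

setValidity("Parcellation", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3) msg <- c(msg, "labels must be a 3-D array")
  if (!is.integer(object@labels)) msg <- c(msg, "labels must be integer")
  else {
    if (any(object@labels < 0L)) msg <- c(msg, "labels must be >= 0")
    if (length(object@L) != 1 || object@L < 1L) msg <- c(msg, "L must be a positive integer")
    else if (max(object@labels) != object@L) msg <- c(msg, "L must equal max(labels)")
  }
  if (!identical(dim(object@affine), c(4L, 4L))) msg <- c(msg, "affine must be 4 x 4")
  if (length(msg)) msg else TRUE
})

#' Construct a Parcellation
#'
#' @param labels 3-D integer (or integer-valued numeric) array; 0 background.
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @return A [Parcellation-class] object.
#' @export
Parcellation <- function(labels, affine = diag(4)) {
  if (is.double(labels)) {
    if (any(labels != round(labels))) stop("label volume is not integer-valued")
    storage.mode(labels) <- "integer"
  }
  new("Parcellation", labels = labels, affine = affine, L = max(labels))
}

#' DistanceFields: per-ROI Euclidean distance transforms
#'
#' One scalar field per label giving, at each voxel center, the Euclidean
#' distance (in voxels) to the nearest voxel of that ROI. Off-grid points are
#' queried by trilinear interpolation with coordinates clamped to the grid.
#'
#' @slot fields named list (one per label "1".."L") of 3-D numeric arrays.
#' @slot dim integer grid dimensions.
#' @export
setClass("DistanceFields", representation(fields = "list", dim = "integer"))

setValidity("DistanceFields", function(object) {
  msg <- character()
  if (length(object@dim) != 3) msg <- c(msg, "dim must have length 3")
  for (nm in names(object@fields)) {
    f <- object@fields[[nm]]
    if (!identical(dim(f), object@dim)) msg <- c(msg, sprintf("field %s has wrong dimensions", nm))
    if (min(f) < 0) msg <- c(msg, sprintf("field %s has negative distances", nm))
  }
  if (length(msg)) msg else TRUE
})

#' BundleModel: centroid curves plus global model variances
#'
#' The bundle model: one centroid curve (m x 3) per occupied ROI pair, with a
#' single isotropic sigma shared by all points of all bundles (sigmaBundle)
#' and the terminal-projection sigma (sigmaRoi), both in voxels.
#'
#' @slot centroids named list of m x 3 matrices; names are canonical bundle
#'   keys "l1-l2" with l1 < l2.
#' @slot sigmaBundle isotropic bundle standard deviation (voxels).
#' @slot sigmaRoi terminal-to-ROI standard deviation (voxels).
#' @slot m number of points per (resampled) curve.
#' @export
setClass("BundleModel", representation(
  centroids = "list", sigmaBundle = "numeric", sigmaRoi = "numeric", m = "integer"
))

setValidity("BundleModel", function(object) {
  msg <- character()
  if (object@sigmaBundle <= 0) msg <- c(msg, "sigmaBundle must be > 0")
  if (object@sigmaRoi <= 0) msg <- c(msg, "sigmaRoi must be > 0")
  for (k in names(object@centroids)) {
    mu <- object@centroids[[k]]
    if (!is.matrix(mu) || !identical(dim(mu), c(object@m, 3L)))
      msg <- c(msg, sprintf("centroid %s is not an m x 3 matrix", k))
    ll <- keyLabels(k)
    if (is.na(ll[1]) || is.na(ll[2]) || ll[1] >= ll[2])
      msg <- c(msg, sprintf("key %s is not canonical (l1 < l2)", k))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BundleModel
#'
#' @param centroids named list of m x 3 centroid matrices keyed by "l1-l2".
#' @param sigmaBundle,sigmaRoi model standard deviations in voxels.
#' @return A [BundleModel-class] object.
#' @export
BundleModel <- function(centroids, sigmaBundle, sigmaRoi) {
  if (length(centroids) == 0) stop("empty bundle model")
  m <- nrow(centroids[[1]])
  new("BundleModel", centroids = centroids, sigmaBundle = sigmaBundle,
      sigmaRoi = sigmaRoi, m = as.integer(m))
}

#' Membership: sparse fiber-to-bundle responsibilities
#'
#' Fiber x bundle responsibility table from an E-step. Entries removed by the
#' 3 sigmaRoi terminal gate are exact zeros and were never evaluated. Each
#' fiber's stored row sums to 1 unless every bundle was gated, in which case
#' the fiber is flagged unassigned. `reversed` records, per (fiber, bundle),
#' whether the fiber was point-reversed to correspond to the centroid; the
#' M-step must average fibers in that orientation.
#'
#' @slot values J x K responsibility matrix (gated entries exactly 0).
#' @slot keys canonical bundle keys (column order).
#' @slot reversed J x K logical orientation matrix.
#' @slot unassigned logical of length J; TRUE when all bundles were gated.
#' @export
setClass("Membership", representation(
  values = "matrix", keys = "character", reversed = "matrix", unassigned = "logical"
))

setValidity("Membership", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@keys)) msg <- c(msg, "keys/value columns mismatch")
  if (any(object@values < 0)) msg <- c(msg, "negative membership")
  rs <- rowSums(object@values)
  ok <- object@unassigned | abs(rs - 1) < 1e-9
  if (!all(ok)) msg <- c(msg, "assigned fiber memberships must sum to 1")
  if (length(msg)) msg else TRUE
})

#' RigidTransform: rotation plus translation
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector.
#' @export
setClass("RigidTransform", representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) msg <- c(msg, "rotation not orthonormal")
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation determinant must be +1")
  }
  if (length(object@translation) != 3) msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' TPSTransform: 3-D thin-plate-spline warp
#'
#' Closed-form thin-plate spline with the 3-D biharmonic kernel U(r) = r.
#' With lambda = 0 the warp interpolates its control points exactly; larger
#' lambda trades fit for smoothness, converging to the weighted affine fit.
#'
#' @slot controls n x 3 control (source) points.
#' @slot W n x 3 kernel coefficients (satisfy t(P) W = 0).
#' @slot A 4 x 3 affine part (row 1 = intercept).
#' @slot lambda regularization weight used in the fit.
#' @export
setClass("TPSTransform", representation(
  controls = "matrix", W = "matrix", A = "matrix", lambda = "numeric"
))

#' GroupModel: common bundle model plus per-subject alignment
#'
#' Result container for groupwise bundling: the common-space bundle model and
#' one transform per subject mapping its native space into the common (label
#' grid) space.
#'
#' @slot model the common [BundleModel-class].
#' @slot transforms list of [RigidTransform-class] or [TPSTransform-class]
#'   (or NULL = identity), one per subject.
#' @slot subjectIDs character vector of subject identifiers.
#' @export
setClass("GroupModel", representation(
  model = "BundleModel", transforms = "list", subjectIDs = "character"
))

setValidity("GroupModel", function(object) {
  if (length(object@transforms) != length(object@subjectIDs))
    "one transform per subject required" else TRUE
})
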