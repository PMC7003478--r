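#' @name parcbundle-accessors
#' @title Accessors for parcbundle classes
#' @description Small accessor generics: number of fibers, fiber list,
#'   bundle keys, centroid curves, label array, label count, and membership
#'   values, in preference to direct slot access.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname parcbundle-accessors
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("fibers", function(x) standardGeneric("fibers"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("bundleKeys", function(x) standardGeneric("bundleKeys"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("nLabels", function(x) standardGeneric("nLabels"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("membershipValues", function(x) standardGeneric("membershipValues"))
#' @rdname parcbundle-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname parcbundle-accessors
#' @param x a FiberSet
#' @export
setMethod("nFibers", "FiberSet", function(x) length(x@fibers))
#' @rdname parcbundle-accessors
#' @export
setMethod("fibers", "FiberSet", function(x) x@fibers)
#' @rdname parcbundle-accessors
#' @export
setMethod("subjectID", "FiberSet", function(x) x@subjectID)
#' @rdname parcbundle-accessors
#' @export
setMethod("labelArray", "Parcellation", function(x) x@labels)
#' @rdname parcbundle-accessors
#' @export
setMethod("nLabels", "Parcellation", function(x) x@L)
#' @rdname parcbundle-accessors
#' @export
setMethod("bundleKeys", "BundleModel", function(x) names(x@centroids))
#' @rdname parcbundle-accessors
#' @export
setMethod("centroids", "BundleModel", function(x) x@centroids)
#' @rdname parcbundle-accessors
#' @export
setMethod("bundleKeys", "Membership", function(x) x@keys)
#' @rdname parcbundle-accessors
#' @export
setMethod("membershipValues", "Membership", function(x) x@values)
#' @rdname parcbundle-accessors
#' @export
setMethod("bundleKeys", "GroupModel", function(x) names(x@model@centroids))
#' @rdname parcbundle-accessors
#' @export
setMethod("centroids", "GroupModel", function(x) x@model@centroids)

#' Warp points through a fitted spatial transform
#'
#' Applies a rigid or thin-plate-spline map to a set of 3-D points,
#' preserving point count and order. `NULL` acts as the identity, so
#' unfitted/identity transforms can be passed around uniformly.
#'
#' @param transform a [RigidTransform-class], [TPSTransform-class], or NULL.
#' @param points n x 3 numeric matrix.
#' @return n x 3 matrix of warped points.
#' @export
setGeneric("warpPoints", function(transform, points) standardGeneric("warpPoints"))

setMethod("show", "FiberSet", function(object) {
  np <- vapply(object@fibers, nrow, 1L)
  cat("FiberSet:", length(object@fibers), "fibers, subject", object@subjectID, "\n")
  if (length(np)) cat("  points per fiber:", min(np), "-", max(np), "\n")
})

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation:", paste(dim(object@labels), collapse = " x "),
      "grid,", object@L, "labels,",
      sum(object@labels > 0L), "foreground voxels\n")
})

setMethod("show", "DistanceFields", function(object) {
  cat("DistanceFields:", length(object@fields), "labels on a",
      paste(object@dim, collapse = " x "), "grid\n")
})

setMethod("show", "BundleModel", function(object) {
  cat("BundleModel:", length(object@centroids), "bundles, m =", object@m,
      ", sigmaBundle =", object@sigmaBundle, ", sigmaRoi =", object@sigmaRoi, "\n")
})

setMethod("show", "Membership", function(object) {
  cat("Membership:", nrow(object@values), "fibers x", length(object@keys),
      "bundles,", sum(object@unassigned), "unassigned\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: translation", paste(signif(object@translation, 4), collapse = ", "), "\n")
})

setMethod("show", "TPSTransform", function(object) {
  cat("TPSTransform:", nrow(object@controls), "control points, lambda =",
      object@lambda, "\n")
})

setMethod("show", "GroupModel", function(object) {
  cat("GroupModel:", length(object@subjectIDs), "subjects,",
      length(object@model@centroids), "common bundles\n")
})
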