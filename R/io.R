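# World <-> voxel conversion. `affine` maps 0-based voxel-center coordinates
# to world mm (NIfTI sform convention).
voxelToWorld <- function(points, affine) {
  points <- stopIfNot3(points)
  sweep(points %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

worldToVoxel0 <- function(points, affine) {
  points <- stopIfNot3(points)
  inv <- solve(affine)
  sweep(points %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

#' Read a NIfTI label volume as a Parcellation
#'
#' @param path NIfTI file (.nii or .nii.gz) holding a 3-D integer-valued
#'   volume; 0 = background, 1..L = ROIs. The number of labels is the
#'   maximum label value; empty intermediate labels are tolerated here and
#'   rejected when distance fields are built.
#' @return A [Parcellation-class] with the file's voxel-to-world affine.
#' @export
readLabels <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("label volume must be 3-D, got ", length(dim(img)), "-D")
  arr <- array(as.numeric(img), dim(img))
  if (any(arr != round(arr))) stop("label volume is not integer-valued")
  Parcellation(arr, affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a Parcellation as a NIfTI label volume
#' @param parc a [Parcellation-class].
#' @param path output file path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeLabels <- function(parc, path) {
  img <- RNifti::asNifti(parc@labels)
  img <- RNifti::`sform<-`(img, structure(parc@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

# ---- TCK (MRtrix tracks) ---------------------------------------------------

#' Read tractography streamlines into label-grid voxel coordinates
#'
#' Reads a TCK (MRtrix) or TRK (TrackVis) streamline file and converts the
#' points into continuous 0-based voxel coordinates of the label grid using
#' the file's spatial metadata composed with the label volume's affine. TCK
#' stores points in world (scanner) mm; TRK stores them in voxel-mm with a
#' corner-of-voxel origin and carries its own voxel-to-world matrix. Fiber
#' order is preserved.
#'
#' @param path .tck or .trk file.
#' @param parc [Parcellation-class] whose grid the fibers are mapped into
#'   (or a 4 x 4 voxel-to-world affine).
#' @param subjectID subject label for the result.
#' @return A [FiberSet-class] (empty file gives an empty set with a warning).
#' @export
readStreamlines <- function(path, parc, subjectID = "subject") {
  affine <- if (is(parc, "Parcellation")) parc@affine else parc
  ext <- tolower(tools::file_ext(path))
  world <- switch(ext,
    tck = readTCK(path),
    trk = readTRK(path),
    stop("unknown streamline format: .", ext, " (expected .tck or .trk)"))
  if (length(world) == 0) {
    warning("no streamlines in ", path)
    return(new("FiberSet", fibers = list(), affine = affine, subjectID = subjectID))
  }
  vox <- lapply(world, function(f) {
    if (any(!is.finite(f))) stop("non-finite points in ", path)
    worldToVoxel0(f, affine)
  })
  FiberSet(vox, affine = affine, subjectID = subjectID)
}

#' Write streamlines from label-grid voxel coordinates
#'
#' Converts fibers back to world mm via the fiber set's affine and writes a
#' TCK or TRK file (chosen by extension).
#'
#' @param fiberSet a [FiberSet-class].
#' @param path output .tck or .trk path.
#' @param dims grid dimensions (required for TRK headers; ignored for TCK).
#' @return `path`, invisibly.
#' @export
writeStreamlines <- function(fiberSet, path, dims = NULL) {
  world <- lapply(fibers(fiberSet), voxelToWorld, affine = fiberSet@affine)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = writeTCK(world, path),
    trk = writeTRK(world, path, affine = fiberSet@affine,
                   dims = if (is.null(dims)) c(0L, 0L, 0L) else dims),
    stop("unknown streamline format: .", ext))
  invisible(path)
}

# TCK: text header, then float32 (x,y,z) triplets in world mm; streamlines
# separated by NaN triplets, stream terminated by an Inf triplet.
readTCK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NULL; dtype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unterminated TCK header")
    if (line == "END") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.integer(strsplit(val, " ")[[1]][2])
    if (key == "datatype") dtype <- val
  }
  if (is.null(offset)) stop("TCK header has no file offset")
  if (!dtype %in% c("Float32LE", "Float32BE")) stop("unsupported TCK datatype: ", dtype)
  endian <- if (dtype == "Float32LE") "little" else "big"
  seek(con, offset)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4, endian = endian)
  pts <- matrix(raw, ncol = 3, byrow = TRUE)
  out <- list()
  start <- 1
  for (i in seq_len(nrow(pts))) {
    if (all(is.nan(pts[i, ])) || all(is.infinite(pts[i, ]))) {
      if (i > start) out[[length(out) + 1]] <- pts[start:(i - 1), , drop = FALSE]
      start <- i + 1
      if (all(is.infinite(pts[i, ]))) break
    }
  }
  out
}

writeTCK <- function(world, path) {
  n <- length(world)
  prefix <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n, "\nfile: . ")
  suffix <- "\nEND\n"
  # the offset field includes its own digit count; grow until consistent
  baseLen <- nchar(prefix, type = "bytes") + nchar(suffix, type = "bytes")
  offset <- baseLen + 1
  repeat {
    total <- baseLen + nchar(as.character(offset))
    if (total <= offset) break
    offset <- total
  }
  header <- paste0(prefix, offset, suffix)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  pad <- offset - nchar(header, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (f in world) {
    writeBin(as.vector(t(f)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

# ---- TRK (TrackVis) --------------------------------------------------------

# TRK stores points in voxel-mm (voxel coordinate * voxel size) with the
# origin at the CORNER of the first voxel, plus a voxel-to-world matrix in
# the header: world = M %*% (voxmm / voxel_size - 0.5, 1).
readTRK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) stop("not a TRK file: ", path)
  readBin(con, "integer", n = 3, size = 2)                   # dim
  voxSize <- readBin(con, "numeric", n = 3, size = 4)
  readBin(con, "numeric", n = 3, size = 4)                   # origin (unused)
  nScalars <- readBin(con, "integer", n = 1, size = 2)
  readBin(con, "raw", n = 200)
  nProps <- readBin(con, "integer", n = 1, size = 2)
  readBin(con, "raw", n = 200)
  M <- matrix(readBin(con, "numeric", n = 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, "raw", n = 444 + 4 + 4 + 24 + 2 + 6)
  nCount <- readBin(con, "integer", n = 1, size = 4)
  readBin(con, "integer", n = 2, size = 4)                   # version, hdr_size
  if (all(M == 0)) { M <- diag(4); M[cbind(1:3, 1:3)] <- voxSize }
  out <- list()
  repeat {
    np <- readBin(con, "integer", n = 1, size = 4)
    if (length(np) == 0) break
    vals <- readBin(con, "numeric", n = np * (3 + nScalars) + nProps, size = 4)
    pm <- matrix(vals[seq_len(np * (3 + nScalars))], ncol = 3 + nScalars, byrow = TRUE)
    vox <- sweep(pm[, 1:3, drop = FALSE], 2, voxSize, "/") - 0.5
    out[[length(out) + 1]] <- sweep(vox %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
    if (nCount > 0 && length(out) >= nCount) break
  }
  out
}

writeTRK <- function(world, path, affine, dims = c(0L, 0L, 0L)) {
  voxSize <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, eos = NULL); writeBin(raw(1), con)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(voxSize, con, size = 4)
  writeBin(rep(0, 3), con, size = 4)                         # origin
  writeBin(0L, con, size = 2); writeBin(raw(200), con)       # scalars
  writeBin(0L, con, size = 2); writeBin(raw(200), con)       # properties
  writeBin(as.numeric(t(affine)), con, size = 4)             # vox_to_ras
  writeBin(raw(444), con)
  writeChar("RAS", con, eos = NULL); writeBin(raw(1), con)   # voxel_order
  writeBin(raw(4 + 24 + 2 + 6), con)
  writeBin(length(world), con, size = 4)
  writeBin(2L, con, size = 4)                                # version
  writeBin(1000L, con, size = 4)                             # hdr_size
  for (f in world) {
    vox <- sweep(f %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
    voxmm <- sweep(vox + 0.5, 2, voxSize, "*")
    writeBin(as.integer(nrow(f)), con, size = 4)
    writeBin(as.vector(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

# ---- run outputs -----------------------------------------------------------

#' Write bundling outputs to a directory
#'
#' Writes the standard output bundle for a [runEM()] (or per-subject
#' [runGroupEM()]) result: a per-fiber assignment table (TSV: fiber_index,
#' l1, l2, membership, reversed), one streamline file per bundle, the
#' centroid streamlines, a metrics JSON, a config snapshot, and serialized
#' transforms when present. Voxel coordinates written to streamline files
#' are converted through the fiber set's affine; all tables use 0-based
#' fiber indices.
#'
#' @param result output of [runEM()].
#' @param fiberSet the [FiberSet-class] the result was computed from.
#' @param dist a [DistanceFields-class] (for the MED metric).
#' @param outdir output directory (created if needed; must be writable).
#' @param format streamline format, `"tck"` (default) or `"trk"`.
#' @param transforms optional list of transforms to serialize.
#' @return `outdir`, invisibly.
#' @export
writeOutputs <- function(result, fiberSet, dist, outdir, format = "tck",
                         transforms = NULL) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory ", outdir)
  probe <- file.path(outdir, ".write-test")
  ok <- tryCatch({ file.create(probe) && file.remove(probe) },
                 warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) stop("output directory ", outdir, " is not writable")

  keys <- result$assignment
  mem <- result$membership
  maxMem <- rep(NA_real_, length(keys))
  if (!is.null(mem) && nrow(mem@values) == length(keys)) {
    ki <- match(keys, mem@keys)
    okk <- !is.na(ki)
    maxMem[okk] <- mem@values[cbind(which(okk), ki[okk])]
  }
  lab <- vapply(keys, function(k)
    if (is.na(k)) c(NA_integer_, NA_integer_) else keyLabels(k), integer(2))
  tab <- data.frame(fiber_index = seq_along(keys) - 1L,
                    l1 = lab[1, ], l2 = lab[2, ],
                    membership = maxMem, reversed = result$reversed)
  utils::write.table(tab, file.path(outdir, "assignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  m <- result$model@m
  fl <- lapply(fibers(fiberSet), ensurePoints, m = m)
  for (k in names(result$model@centroids)) {
    jj <- which(!is.na(keys) & keys == k)
    if (!length(jj)) next
    fs <- new("FiberSet", fibers = fl[jj], affine = fiberSet@affine,
              subjectID = fiberSet@subjectID)
    writeStreamlines(fs, file.path(outdir, paste0("bundle_", k, ".", format)),
                     dims = dist@dim)
  }
  centsFS <- new("FiberSet", fibers = unname(result$model@centroids),
                 affine = fiberSet@affine, subjectID = "centroids")
  writeStreamlines(centsFS, file.path(outdir, paste0("centroids.", format)),
                   dims = dist@dim)

  miv <- meanInbundleVariation(fiberSet, keys, result$model)
  med <- meanEndToRoiDistance(fiberSet, keys, dist, m = m)
  counts <- table(factor(keys, levels = names(result$model@centroids)))
  metrics <- list(MIV = as.numeric(miv), MED = as.numeric(med),
                  unassigned = result$unassigned,
                  iterations = nrow(result$trace),
                  bundles = as.list(counts))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(result$config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(result$trace) && nrow(result$trace))
    utils::write.table(result$trace, file.path(outdir, "trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(transforms))
    jsonlite::write_json(lapply(transforms, transformToList),
                         file.path(outdir, "transforms.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a subject manifest
#'
#' Tab-separated file with columns `subject_id` and `file` (streamline path,
#' relative paths resolved against the manifest's directory).
#'
#' @param path manifest TSV.
#' @param parc [Parcellation-class] used to map all subjects.
#' @return list of [FiberSet-class].
#' @export
readSubjectManifest <- function(path, parc) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "file") %in% names(tab)))
    stop("manifest needs columns subject_id and file")
  lapply(seq_len(nrow(tab)), function(i) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(dirname(path), f)
    readStreamlines(f, parc, subjectID = as.character(tab$subject_id[i]))
  })
}
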