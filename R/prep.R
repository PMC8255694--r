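# NIfTI I/O and non-destructive preprocessing: auto-crop -> zero-mean /
# unit-SD normalisation -> zero padding to lattice dimensions divisible by
# 2^(N-1), with an exact inverse back to native space via a PrepRecord.

canonicalOrientation <- "LAS"

# Reorient to the canonical convention where the header carries a usable
# xform; images without one (qform/sform codes both zero) pass through.
canonicalize <- function(img) {
  suppressWarnings(tryCatch({
    if (!identical(RNifti::orientation(img), canonicalOrientation))
      RNifti::orientation(img) <- canonicalOrientation
    img
  }, error = function(e) img))
}

#' Read and write NIfTI-1 volumes and masks
#'
#' Volumes are canonicalized to one anatomical axis convention (LAS) on
#' read. Masks must be strictly binary: any other value is an error, never
#' silently binarized. Mask round-trips are bit exact; intensity volumes
#' round-trip at float precision (they are written as doubles).
#'
#' @param path a .nii or .nii.gz file.
#' @param subjectId,cohortId,timepoint identity attached to the object.
#' @return \code{readVolume}: a [HeadVolume-class]; \code{readMask}: an
#'   [ICCMask-class].
#' @export
readVolume <- function(path, subjectId = NA_character_, cohortId = NA_character_,
                       timepoint = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- canonicalize(RNifti::readNifti(path))
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  arr <- array(as.numeric(img), dim(img))
  if (!all(is.finite(arr))) stop("non-finite voxels in ", path)
  sp <- RNifti::pixdim(img)[1:3]
  new("HeadVolume", voxels = arr, spacing = as.numeric(sp),
      subjectId = subjectId, cohortId = cohortId,
      timepoint = as.integer(timepoint))
}

#' @rdname readVolume
#' @export
readMask <- function(path, subjectId = NA_character_, cohortId = NA_character_,
                     timepoint = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- canonicalize(RNifti::readNifti(path))
  if (length(dim(img)) != 3L)
    stop("expected a 3D mask, got ", length(dim(img)), "D: ", path)
  arr <- array(as.numeric(img), dim(img))
  if (!all(arr %in% c(0, 1)))
    stop("mask has values outside {0, 1}: ", path)
  new("ICCMask", voxels = array(as.integer(arr), dim(arr)),
      spacing = as.numeric(RNifti::pixdim(img)[1:3]),
      subjectId = subjectId, cohortId = cohortId,
      timepoint = as.integer(timepoint))
}

#' @rdname readVolume
#' @param vol a [HeadVolume-class]. @param mask an [ICCMask-class].
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@voxels)
  RNifti::qform(img) <- lasAffine(vol@spacing)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Canonical-orientation affine: increasing i moves Left, j Anterior, k
# Superior (world frame is RAS, hence the negated first axis).
lasAffine <- function(spacing) {
  structure(diag(c(-spacing[1], spacing[2], spacing[3], 1)), code = 2L)
}

#' @rdname readVolume
#' @export
writeMask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask@voxels), dim(mask@voxels)))
  RNifti::qform(img) <- lasAffine(mask@spacing)
  RNifti::pixdim(img) <- mask@spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Auto-crop a volume to its foreground bounding box
#'
#' Foreground is detected as voxels above \code{fgFraction} of the
#' 99th-percentile intensity, cleaned by a 3x3x3 morphological opening
#' (removing isolated noise voxels) followed by a closing (filling interior
#' gaps), and reduced to the largest 6-connected component; the crop is
#' that component's tight bounding box expanded by \code{margin} voxels
#' (clamped to the lattice).
#'
#' @param vol a [HeadVolume-class] with at least one foreground voxel.
#' @param margin voxels added around the bounding box (default 2).
#' @param fgFraction foreground threshold as a fraction of the
#'   99th-percentile intensity (default 0.1).
#' @return list(volume = cropped HeadVolume, cropStart, cropStop) with
#'   0-based half-open crop indices.
#' @export
autocrop <- function(vol, margin = 2L, fgFraction = 0.1) {
  v <- vol@voxels
  thr <- fgFraction * quantile(v, 0.99, names = FALSE)
  fg <- array(as.integer(v > thr), dim(v))
  if (!any(fg == 1L)) stop("all-background volume: nothing to crop")
  fg <- cpp_boxclose(cpp_boxopen(fg))
  if (!any(fg == 1L)) stop("no foreground component survives morphological cleaning")
  lab <- cpp_label6(fg)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  idx <- which(lab == keep, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(v))
  cropped <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- vol
  out@voxels <- cropped
  list(volume = out, cropStart = as.integer(lo - 1L), cropStop = as.integer(hi))
}

#' Normalize intensities to zero mean and unit SD
#'
#' Statistics are computed over all voxels of the (cropped) lattice, with
#' the population SD (so e.g. equal numbers of 0 and 2 map exactly to -1
#' and +1); the recorded mean and SD allow exact de-normalization.
#'
#' @param vol a [HeadVolume-class] with non-constant intensities.
#' @return list(volume, normMean, normSd).
#' @export
normalizeIntensity <- function(vol) {
  m <- mean(vol@voxels)
  s <- sqrt(mean((vol@voxels - m)^2))
  if (!is.finite(s) || s <= 0) stop("constant image: SD is zero, cannot normalize")
  out <- vol
  out@voxels <- (vol@voxels - m) / s
  list(volume = out, normMean = m, normSd = s)
}

#' Zero-pad to stage-compatible dimensions
#'
#' Pads each axis with zeros to the smallest multiple of 2^(N-1) at least
#' the current size, split as evenly as possible with the extra voxel after
#' the data, so N-stage max-pooling halves the lattice exactly N-1 times.
#'
#' @param vol a [HeadVolume-class]. @param nStages stage count N in 2..5.
#' @return list(volume, padBefore, padAfter).
#' @export
padToStageMultiple <- function(vol, nStages) {
  if (!(nStages %in% 2:5)) stop("nStages must be in 2..5")
  m <- 2L^(as.integer(nStages) - 1L)
  d <- dim(vol@voxels)
  target <- as.integer(ceiling(d / m) * m)
  pad <- target - d
  before <- pad %/% 2L
  after <- pad - before
  out <- vol
  out@voxels <- padArray(vol@voxels, before, after)
  list(volume = out, padBefore = as.integer(before), padAfter = as.integer(after))
}

padArray <- function(arr, before, after, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d + before + after)
  out[before[1] + seq_len(d[1]), before[2] + seq_len(d[2]), before[3] + seq_len(d[3])] <- arr
  out
}

#' Preprocess a native volume for the network
#'
#' Composition, in this exact order: auto-crop, zero-mean/unit-SD
#' normalisation over the cropped lattice, zero padding to dimensions
#' divisible by 2^(N-1). The normalisation statistics therefore exclude the
#' padded zeros. The returned [PrepRecord-class] inverts every step.
#'
#' @inheritParams autocrop
#' @param nStages stage count N of the target network.
#' @return list(volume = network-space HeadVolume, record = PrepRecord).
#' @export
preprocess <- function(vol, nStages, margin = 2L, fgFraction = 0.1) {
  cr <- autocrop(vol, margin = margin, fgFraction = fgFraction)
  nm <- normalizeIntensity(cr$volume)
  pd <- padToStageMultiple(nm$volume, nStages)
  rec <- new("PrepRecord", nativeDims = dim(vol@voxels),
             cropStart = cr$cropStart, cropStop = cr$cropStop,
             padBefore = pd$padBefore, padAfter = pd$padAfter,
             normMean = nm$normMean, normSd = nm$normSd,
             nStages = as.integer(nStages))
  list(volume = pd$volume, record = rec)
}

# Carry a ground-truth mask into network space: crop with the volume's
# record and zero-pad (no normalisation).  Used to align training targets.
prepMaskArray <- function(maskArr, rec) {
  lo <- rec@cropStart + 1L
  hi <- rec@cropStop
  cropped <- maskArr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  padArray(cropped, rec@padBefore, rec@padAfter)
}

#' Restore a network-space lattice to native space
#'
#' Removes the padding, re-embeds the crop region at its native offset and
#' fills everything outside the crop box with 0 (background / non-ICC).
#' For masks this is a bit-exact inverse of crop+pad within the crop box.
#'
#' @param x a 3D array, [ProbMap-class] or [ICCMask-class] whose dimensions
#'   equal the record's padded network-space dimensions.
#' @param rec the [PrepRecord-class] from [preprocess()].
#' @return object of the same kind as \code{x} with native dimensions.
#' @export
restoreNative <- function(x, rec) {
  arr <- if (is(x, "ProbMap") || is(x, "ICCMask")) x@voxels else x
  expected <- (rec@cropStop - rec@cropStart) + rec@padBefore + rec@padAfter
  if (!identical(dim(arr), as.integer(expected)))
    stop(sprintf("lattice dims (%s) do not match record's network-space dims (%s)",
                 paste(dim(arr), collapse = "x"), paste(expected, collapse = "x")))
  cropDims <- rec@cropStop - rec@cropStart
  b <- rec@padBefore
  inner <- arr[b[1] + seq_len(cropDims[1]), b[2] + seq_len(cropDims[2]),
               b[3] + seq_len(cropDims[3]), drop = FALSE]
  native <- array(if (is.integer(inner)) 0L else 0, rec@nativeDims)
  lo <- rec@cropStart
  native[lo[1] + seq_len(cropDims[1]), lo[2] + seq_len(cropDims[2]),
         lo[3] + seq_len(cropDims[3])] <- inner
  if (is(x, "ProbMap")) { x@voxels <- native; x }
  else if (is(x, "ICCMask")) { x@voxels <- native; x }
  else native
}
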