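# End-to-end prediction: preprocess -> forward with EMA weights -> restore
# to native space -> threshold; plus empirical threshold calibration.

#' Predict a native-space probability map
#'
#' Preprocesses the volume for the checkpoint's stage count, runs the
#' forward pass with the EMA weights, and restores the fused map to native
#' space; voxels outside the crop box get probability 0. Deterministic
#' given checkpoint and input.
#'
#' @param state a [TrainState-class] (or loaded checkpoint).
#' @param vol a native-space [HeadVolume-class].
#' @param useEma use the EMA weights (default) rather than current weights.
#' @return a [ProbMap-class] with the volume's native dims and spacing.
#' @export
predictProbmap <- function(state, vol, useEma = TRUE) {
  net <- state@network
  pp <- preprocess(vol, net@config@nStages)
  w <- if (useEma) state@emaWeights else net@weights
  fwd <- forwardPass(net, pp$volume@voxels, weights = w)
  fused <- pmin(pmax(fwd$fused, 0), 1)
  native <- restoreNative(fused, pp$record)
  new("ProbMap", voxels = native, spacing = vol@spacing,
      provenance = sprintf("ema=%s step=%d", useEma, state@step))
}

#' Binarize a probability map
#'
#' A voxel is included iff its probability strictly exceeds the threshold
#' (the production rule is p > 0.34).
#'
#' @param map a [ProbMap-class].
#' @param threshold probability threshold in (0, 1); default 0.34, the
#'   empirically calibrated production value.
#' @param strict use strict inequality (default TRUE).
#' @param keepLargestComponent off by default (no connected-component
#'   postprocessing is part of the production rule); when TRUE, retain only
#'   the largest 6-connected component of the thresholded mask.
#' @return an [ICCMask-class].
#' @export
binarize <- function(map, threshold = 0.34, strict = TRUE,
                     keepLargestComponent = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  v <- if (strict) map@voxels > threshold else map@voxels >= threshold
  v <- array(as.integer(v), dim(map@voxels))
  if (keepLargestComponent && any(v == 1L)) {
    lab <- cpp_label6(v)
    v <- array(as.integer(lab == which.max(tabulate(lab[lab > 0L]))), dim(v))
  }
  new("ICCMask", voxels = v, spacing = map@spacing)
}

#' Mask volume in cubic centimetres
#'
#' @param mask an [ICCMask-class].
#' @return count of 1-voxels times the voxel volume (product of spacings,
#'   mm^3), divided by 1000.
#' @export
maskVolumeCm3 <- function(mask) {
  sum(mask@voxels) * prod(mask@spacing) / 1000
}

#' Calibrate the binarization threshold on an evaluation set
#'
#' Sweeps a threshold grid and selects the value maximizing the median
#' Dice score, breaking ties by the smaller DSC interquartile range, then
#' by the lower threshold. \code{calibrateFromProbMaps} performs the sweep
#' on precomputed maps; \code{calibrateThreshold} predicts the maps from a
#' checkpoint first.
#'
#' @param probMaps list of [ProbMap-class]. @param gtMasks list of
#'   [ICCMask-class] aligned with \code{probMaps}.
#' @param grid thresholds to sweep (default 0.01..0.99 step 0.01).
#' @return list(threshold, table) where table has one row per grid value
#'   with the median and IQR of DSC across the evaluation pairs.
#' @export
calibrateFromProbMaps <- function(probMaps, gtMasks, grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(probMaps) < 2L) stop("threshold calibration needs >= 2 evaluation pairs")
  stopifnot(length(probMaps) == length(gtMasks), length(grid) >= 1L)
  tab <- data.frame(threshold = grid, medianDsc = NA_real_, iqrDsc = NA_real_)
  for (i in seq_along(grid)) {
    dscs <- mapply(function(p, g) {
      pred <- binarize(p, grid[i])
      if (sum(pred@voxels) + sum(g@voxels) == 0) return(NA_real_)
      if (sum(pred@voxels) == 0 || sum(g@voxels) == 0)
        return(0)  # no overlap possible
      dice(pred, g)
    }, probMaps, gtMasks)
    qs <- quantile(dscs, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tab$medianDsc[i] <- qs[2]
    tab$iqrDsc[i] <- qs[3] - qs[1]
  }
  tol <- 1e-12
  best <- which(tab$medianDsc > max(tab$medianDsc) - tol)
  best <- best[tab$iqrDsc[best] < min(tab$iqrDsc[best]) + tol]
  best <- best[1L]  # lowest threshold among remaining ties (grid is sorted)
  list(threshold = tab$threshold[best], table = tab)
}

#' @rdname calibrateFromProbMaps
#' @param state a [TrainState-class].
#' @param evalPairs list of list(volume = HeadVolume, mask = ICCMask).
#' @export
calibrateThreshold <- function(state, evalPairs, grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(evalPairs) < 2L) stop("threshold calibration needs >= 2 evaluation pairs")
  maps <- lapply(evalPairs, function(p) predictProbmap(state, p$volume))
  gts <- lapply(evalPairs, function(p) p$mask)
  calibrateFromProbMaps(maps, gts, grid)
}
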