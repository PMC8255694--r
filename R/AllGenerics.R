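#' Accessors for lattice-backed objects
#'
#' \code{voxelData} returns the raw 3D array, \code{voxelSpacing} the
#' per-axis voxel edge lengths in mm.
#'
#' @param x a [HeadVolume], [ICCMask] or [ProbMap].
#' @return \code{voxelData}: a 3D array; \code{voxelSpacing}: numeric(3).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

for (cl in c("HeadVolume", "ICCMask", "ProbMap")) {
  setMethod("voxelData", cl, function(x) x@voxels)
  setMethod("voxelSpacing", cl, function(x) x@spacing)
}

setMethod("show", "HeadVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("HeadVolume %s/%s t%d: %dx%dx%d voxels @ %s mm, range [%.3g, %.3g]\n",
              object@cohortId, object@subjectId, object@timepoint,
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "ICCMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ICCMask %s/%s t%d: %dx%dx%d voxels @ %s mm, |mask| = %d (%.2f cm^3)\n",
              object@cohortId, object@subjectId, object@timepoint,
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
              sum(object@voxels), maskVolumeCm3(object)))
})

setMethod("show", "ProbMap", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ProbMap: %dx%dx%d voxels @ %s mm, values in [%.3f, %.3f]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = "x"),
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "PrepRecord", function(object) {
  cat(sprintf(paste0("PrepRecord: native %s, crop [%s)-[%s), pad %s+%s, ",
                     "mean %.4g sd %.4g, N = %d stages\n"),
              paste(object@nativeDims, collapse = "x"),
              paste(object@cropStart, collapse = ","),
              paste(object@cropStop, collapse = ","),
              paste(object@padBefore, collapse = ","),
              paste(object@padAfter, collapse = ","),
              object@normMean, object@normSd, object@nStages))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec '%s': %d subjects x %d timepoints, %s lattice @ %s mm,\n",
                     "  noise %.3g, bias %.3g, ICC semi-axes [%s]-[%s] mm, ",
                     "pose <= %.3g deg / %.3g mm, seed %d\n"),
              object@cohortId, object@nSubjects, object@nTimepoints,
              paste(object@dims, collapse = "x"),
              paste(signif(object@voxelSpacing, 3), collapse = "x"),
              object@noiseSigma, object@biasAmplitude,
              paste(signif(object@radiiMin, 3), collapse = ","),
              paste(signif(object@radiiMax, 3), collapse = ","),
              object@maxRotDeg, object@maxTransMm, object@seed))
})

setMethod("show", "Network", function(object) {
  s <- summarizeArchitecture(object)
  cat(sprintf(paste0("Deeply supervised segmentation Network: %d stages, ",
                     "%d encoder convs, %d pools, %d decoder convs, ",
                     "%s trainable parameters\n"),
              object@config@nStages, s$encoderConvCount, s$poolCount,
              s$decoderConvCount, format(s$parameterCount, big.mark = ",")))
})

setMethod("show", "TrainState", function(object) {
  n <- nrow(object@lossHistory)
  last <- if (n) mean(tail(object@lossHistory$loss, min(50L, n))) else NA_real_
  cat(sprintf("TrainState: %d steps completed; mean loss over last %d steps: %.4g\n",
              object@step, min(50L, n), last))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d images, %d cohorts\n", nrow(object@perImage),
              length(unique(object@perImage$cohort))))
  ov <- object@summary[object@summary$cohort == "overall" & object@summary$metric == "dsc", ]
  if (nrow(ov))
    cat(sprintf("  overall DSC median %.4f, mean %.4f, SD %.4f\n",
                ov$median, ov$mean, ov$sd))
})

setMethod("show", "LongitudinalReport", function(object) {
  cat(sprintf("LongitudinalReport: %d subjects, median max volume difference %.3f cm^3\n",
              nrow(object@perSubject), object@medianMaxDiffCm3))
})
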