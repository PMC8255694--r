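# Evaluation battery: Dice, symmetric Hausdorff distance in mm,
# false-negative/false-positive percentages, percent volume difference,
# longitudinal consistency and cohort-stratified aggregation.

checkAligned <- function(A, B) {
  if (!identical(dim(A@voxels), dim(B@voxels)))
    stop("masks have different dimensions")
  if (!isTRUE(all.equal(A@spacing, B@spacing)))
    stop("masks have different voxel spacing")
}

#' Dice similarity coefficient
#'
#' DSC = 2 |A intersect B| / (|A| + |B|), the standard overlap measure in
#' [0, 1]; symmetric, 1 exactly on identical non-empty masks.
#'
#' @param A,B aligned [ICCMask-class] objects, not both empty.
#' @return numeric in [0, 1].
#' @export
dice <- function(A, B) {
  checkAligned(A, B)
  a <- sum(A@voxels)
  b <- sum(B@voxels)
  if (a + b == 0) stop("DSC undefined: both masks are empty")
  i <- sum(A@voxels * B@voxels)
  2 * i / (a + b)
}

#' Symmetric Hausdorff distance in millimetres
#'
#' HD = max(h(A,B), h(B,A)) with h(A,B) = max over a in A of the minimum
#' Euclidean distance (voxel indices scaled by the per-axis spacing) to any
#' b in B. Computed exactly via Euclidean distance transforms of each mask
#' evaluated at the other's voxels, which equals the double-loop
#' definition.
#'
#' @param A,B aligned non-empty [ICCMask-class] objects.
#' @return distance in mm, 0 exactly on identical masks.
#' @export
hausdorffMM <- function(A, B) {
  checkAligned(A, B)
  if (sum(A@voxels) == 0 || sum(B@voxels) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  intArr <- function(a) if (is.integer(a)) a else array(as.integer(a), dim(a))
  dToB <- cpp_edt_sq(intArr(B@voxels), A@spacing)
  dToA <- cpp_edt_sq(intArr(A@voxels), A@spacing)
  hAB <- sqrt(max(dToB[A@voxels == 1L]))
  hBA <- sqrt(max(dToA[B@voxels == 1L]))
  max(hAB, hBA)
}

#' False-negative and false-positive percentages
#'
#' \code{falseNegativePct}: percentage of the ground-truth mask missed by
#' the prediction, 100 |gt \\ pred| / |gt|. \code{falsePositivePct}:
#' percentage of the prediction lying outside the ground truth,
#' 100 |pred \\ gt| / |pred|.
#'
#' @param pred,gt aligned [ICCMask-class] objects; \code{gt} must be
#'   non-empty for FN, \code{pred} non-empty for FP.
#' @return percentage in [0, 100].
#' @export
falseNegativePct <- function(pred, gt) {
  checkAligned(pred, gt)
  g <- sum(gt@voxels)
  if (g == 0) stop("FN% undefined: ground-truth mask is empty")
  100 * sum(gt@voxels * (1L - pred@voxels)) / g
}

#' @rdname falseNegativePct
#' @export
falsePositivePct <- function(pred, gt) {
  checkAligned(pred, gt)
  p <- sum(pred@voxels)
  if (p == 0) stop("FP% undefined: prediction mask is empty")
  100 * sum(pred@voxels * (1L - gt@voxels)) / p
}

#' Signed percent volume difference
#'
#' 100 * (vol(pred) - vol(gt)) / vol(gt), volumes in cm^3.
#'
#' @param pred,gt aligned [ICCMask-class] objects; \code{gt} non-empty.
#' @return signed percentage.
#' @export
volumeDiffPct <- function(pred, gt) {
  checkAligned(pred, gt)
  vg <- maskVolumeCm3(gt)
  if (vg == 0) stop("volume difference undefined: ground-truth mask is empty")
  100 * (maskVolumeCm3(pred) - vg) / vg
}

#' Longitudinal maximum volume difference
#'
#' For each subject with serial scans, the maximum minus the minimum mask
#' volume over all scans, in cm^3; estimated ICC volumes are expected to be
#' unchanged over repeated scans, so this measures segmentation
#' consistency.
#'
#' @param masksBySubject named list: subject id -> list of >= 2
#'   [ICCMask-class] objects (one per timepoint).
#' @return a [LongitudinalReport-class].
#' @export
longitudinalMaxDiff <- function(masksBySubject) {
  if (length(masksBySubject) == 0) stop("no subjects given")
  rows <- lapply(names(masksBySubject), function(sid) {
    masks <- masksBySubject[[sid]]
    if (length(masks) < 2L)
      stop("subject ", sid, " has fewer than 2 timepoints")
    vols <- vapply(masks, maskVolumeCm3, numeric(1))
    data.frame(subject = sid, nTimepoints = length(vols),
               minVolCm3 = min(vols), maxVolCm3 = max(vols),
               maxDiffCm3 = max(vols) - min(vols), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  new("LongitudinalReport", perSubject = per,
      medianMaxDiffCm3 = median(per$maxDiffCm3))
}

aggRows <- function(df, metrics, label) {
  out <- lapply(metrics, function(m) {
    v <- df[[m]][!is.na(df[[m]])]
    n <- length(v)
    data.frame(cohort = label, metric = m, n = n,
               median = median(v), mean = mean(v),
               sd = if (n > 1) sd(v) else 0,
               sdDefined = n > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate a set of prediction/ground-truth pairs
#'
#' Computes per-image DSC, Hausdorff distance (mm), FN%, FP% and percent
#' volume difference, then aggregates (median, mean, sample SD) per cohort
#' and overall. Groups of size 1 report SD = 0 with \code{sdDefined =
#' FALSE}.
#'
#' @param preds,gts aligned lists of [ICCMask-class] objects.
#' @param subjects,cohorts,timepoints optional per-pair identity vectors;
#'   defaults come from the ground-truth masks.
#' @param hausdorff compute the Hausdorff distance (set FALSE to skip the
#'   most expensive metric in large sweeps).
#' @param onEmptyPred \code{"error"} (default, the production QC policy:
#'   an empty prediction surfaces loudly) or \code{"score"}: score the
#'   image with DSC 0, FN 100, volume difference -100 and undefined
#'   (NA) Hausdorff/FP, as the experiment harness does for undertrained
#'   sweep models.
#' @return an [EvalReport-class].
#' @export
evaluateSet <- function(preds, gts, subjects = NULL, cohorts = NULL,
                        timepoints = NULL, hausdorff = TRUE,
                        onEmptyPred = c("error", "score")) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1L)
  onEmptyPred <- match.arg(onEmptyPred)
  n <- length(preds)
  if (is.null(subjects)) subjects <- vapply(gts, function(g) g@subjectId, character(1))
  if (is.null(cohorts)) cohorts <- vapply(gts, function(g) g@cohortId, character(1))
  if (is.null(timepoints)) timepoints <- vapply(gts, function(g) g@timepoint, integer(1))
  rows <- lapply(seq_len(n), function(i) {
    p <- preds[[i]]; g <- gts[[i]]
    if (sum(p@voxels) == 0 && onEmptyPred == "score")
      return(data.frame(subject = subjects[i], cohort = cohorts[i],
                        timepoint = timepoints[i], dsc = 0, hdMM = NA_real_,
                        fnPct = 100, fpPct = NA_real_, volDiffPct = -100,
                        stringsAsFactors = FALSE))
    data.frame(subject = subjects[i], cohort = cohorts[i],
               timepoint = timepoints[i],
               dsc = dice(p, g),
               hdMM = if (hausdorff) hausdorffMM(p, g) else NA_real_,
               fnPct = falseNegativePct(p, g),
               fpPct = falsePositivePct(p, g),
               volDiffPct = volumeDiffPct(p, g), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  metrics <- c("dsc", if (hausdorff) "hdMM", "fnPct", "fpPct", "volDiffPct")
  summ <- do.call(rbind, c(
    lapply(sort(unique(per$cohort)), function(cid)
      aggRows(per[per$cohort == cid, , drop = FALSE], metrics, cid)),
    list(aggRows(per, metrics, "overall"))))
  rownames(summ) <- NULL
  new("EvalReport", perImage = per, summary = summ)
}
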