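#' @import methods
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils head tail read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib iccseg, .registration = TRUE
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' HeadVolume: a whole-head 3D intensity lattice
#'
#' Holds a 3D scalar intensity lattice together with per-axis voxel spacing
#' in millimetres and subject/cohort/timepoint identity strings. This is the
#' container every preprocessing, training and inference operation consumes.
#'
#' @slot voxels 3D numeric array of intensities (finite values only).
#' @slot spacing numeric(3), per-axis voxel edge length in mm (all > 0).
#' @slot subjectId,cohortId character scalars identifying the scan.
#' @slot timepoint integer scalar, 1-based scan index within a subject.
#' @export
setClass("HeadVolume",
  representation(voxels = "array", spacing = "numeric",
                 subjectId = "character", cohortId = "character",
                 timepoint = "integer"),
  prototype(spacing = c(1, 1, 1), subjectId = NA_character_,
            cohortId = NA_character_, timepoint = 1L))

setValidity("HeadVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  if (!all(is.finite(object@voxels))) msg <- c(msg, "voxels must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' ICCMask: a binary intracranial-cavity mask
#'
#' A binary (0/1) lattice aligned voxel-for-voxel with a [HeadVolume]. Masks
#' are the segmentation target during training and the segmentation output
#' after thresholding; they hold the voxel sets compared by [dice()] and
#' [hausdorffMM()].
#'
#' @slot voxels 3D integer array over \{0, 1\}.
#' @slot spacing numeric(3) voxel spacing in mm, inherited from the volume.
#' @slot subjectId,cohortId character scalars; @slot timepoint integer.
#' @export
setClass("ICCMask",
  representation(voxels = "array", spacing = "numeric",
                 subjectId = "character", cohortId = "character",
                 timepoint = "integer"),
  prototype(spacing = c(1, 1, 1), subjectId = NA_character_,
            cohortId = NA_character_, timepoint = 1L))

setValidity("ICCMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  if (!all(object@voxels %in% c(0L, 1L))) msg <- c(msg, "mask values must be 0 or 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' ProbMap: per-voxel brain-membership strength
#'
#' The fused network output restored to native space: one value in [0, 1]
#' per voxel estimating the strength of ICC membership. Binarised by
#' [binarize()] using the empirically calibrated threshold.
#'
#' @slot voxels 3D numeric array with values in [0, 1].
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot provenance character, free-form origin tag (checkpoint id etc.).
#' @export
setClass("ProbMap",
  representation(voxels = "array", spacing = "numeric",
                 provenance = "characterOrNULL"),
  prototype(spacing = c(1, 1, 1), provenance = NULL))

setValidity("ProbMap", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
  rng <- range(object@voxels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PrepRecord: invertible record of preprocessing
#'
#' Records everything needed to map a padded, normalised network-space
#' lattice back to the native scan: the native dimensions, the 0-based
#' half-open crop interval, per-axis pad amounts, the normalisation mean/SD
#' and the stage count whose divisibility rule the padding satisfies.
#' Preprocessing is non-destructive: [restoreNative()] inverts it exactly.
#'
#' @slot nativeDims integer(3) dimensions of the native lattice.
#' @slot cropStart,cropStop integer(3), 0-based half-open crop interval.
#' @slot padBefore,padAfter integer(3) zero-padding added per axis.
#' @slot normMean,normSd normalisation constants (SD > 0).
#' @slot nStages integer, stage count N of the target network (dims of the
#'   cropped-plus-padded lattice are divisible by 2^(N-1)).
#' @export
setClass("PrepRecord",
  representation(nativeDims = "integer", cropStart = "integer",
                 cropStop = "integer", padBefore = "integer",
                 padAfter = "integer", normMean = "numeric",
                 normSd = "numeric", nStages = "integer"))

setValidity("PrepRecord", function(object) {
  msg <- character()
  if (any(object@cropStart < 0L) || any(object@cropStop > object@nativeDims) ||
      any(object@cropStop <= object@cropStart))
    msg <- c(msg, "crop interval must lie within native dims and be non-empty")
  if (length(object@normSd) && object@normSd <= 0) msg <- c(msg, "normSd must be > 0")
  if (length(object@nStages)) {
    m <- 2L^(object@nStages - 1L)
    d <- (object@cropStop - object@cropStart) + object@padBefore + object@padAfter
    if (any(d %% m != 0L))
      msg <- c(msg, sprintf("cropped+padded dims must be divisible by %d", m))
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of one synthetic imaging cohort
#'
#' A cohort emulates one imaging study: a shared contrast profile (tissue
#' means), noise level, bias-field strength, head-size range, pose range,
#' voxel spacing and lattice size. Two specs with identical fields generate
#' identical data streams; all randomness derives from \code{seed}.
#'
#' @slot cohortId short identifier string.
#' @slot nSubjects number of subjects in the cohort (>= 1).
#' @slot nTimepoints scans per subject (>= 1; > 1 yields longitudinal series).
#' @slot tissueMeans named numeric with entries background, scalp, skull,
#'   csf, brain (arbitrary intensity units).
#' @slot noiseSigma additive Gaussian noise SD (intensity units, >= 0).
#' @slot biasAmplitude peak multiplicative deviation of the smooth bias
#'   field, in [0, 1].
#' @slot radiiMin,radiiMax per-axis min/max ICC semi-axis lengths (mm).
#' @slot maxRotDeg,maxTransMm pose range: max rotation (degrees) and
#'   translation (mm) per axis.
#' @slot voxelSpacing numeric(3) mm; @slot dims integer(3) lattice size.
#' @slot seed integer RNG seed for the cohort's data stream.
#' @export
setClass("CohortSpec",
  representation(cohortId = "character", nSubjects = "integer",
                 nTimepoints = "integer", tissueMeans = "numeric",
                 noiseSigma = "numeric", biasAmplitude = "numeric",
                 radiiMin = "numeric", radiiMax = "numeric",
                 maxRotDeg = "numeric", maxTransMm = "numeric",
                 voxelSpacing = "numeric", dims = "integer",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  need <- c("background", "scalp", "skull", "csf", "brain")
  if (!all(need %in% names(object@tissueMeans)))
    msg <- c(msg, paste("tissueMeans must name:", paste(need, collapse = ", ")))
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nTimepoints < 1L) msg <- c(msg, "nTimepoints must be >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude > 1)
    msg <- c(msg, "biasAmplitude must lie in [0, 1]")
  if (length(object@radiiMin) != 3L || length(object@radiiMax) != 3L ||
      any(object@radiiMin <= 0) || any(object@radiiMax < object@radiiMin))
    msg <- c(msg, "radii must satisfy 0 < min <= max per axis")
  if (object@maxRotDeg < 0 || object@maxTransMm < 0)
    msg <- c(msg, "pose ranges must be >= 0")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 positive values")
  if (length(object@dims) != 3L || any(object@dims < 8L))
    msg <- c(msg, "dims must be 3 values >= 8")
  if (length(msg)) msg else TRUE
})

#' NetConfig: architecture configuration
#'
#' Parameterises the deeply supervised encoder/fuse-decoder network: stage
#' count N in 2..5, per-stage conv-layer counts, per-stage filter counts, and
#' a width multiplier that scales every filter count for desk-scale runs.
#'
#' @slot nStages integer in 2..5.
#' @slot convCounts,filterCounts integer vectors of length nStages.
#' @slot widthMultiplier positive scaling applied to filterCounts.
#' @slot seed integer weight-initialisation seed.
#' @export
setClass("NetConfig",
  representation(nStages = "integer", convCounts = "integer",
                 filterCounts = "integer", widthMultiplier = "numeric",
                 seed = "integer"))

setValidity("NetConfig", function(object) {
  msg <- character()
  if (!(object@nStages %in% 2:5)) msg <- c(msg, "nStages must be in 2..5")
  if (length(object@convCounts) != object@nStages ||
      length(object@filterCounts) != object@nStages)
    msg <- c(msg, "convCounts and filterCounts must have length nStages")
  if (any(object@filterCounts < 1L)) msg <- c(msg, "scaled filter counts must be >= 1")
  if (object@widthMultiplier <= 0) msg <- c(msg, "widthMultiplier must be > 0")
  if (length(msg)) msg else TRUE
})

#' Network: a constructed deeply supervised segmentation network
#'
#' Built by [buildNetwork()]. Carries the configuration, an ordered layer
#' descriptor list (traversed by [summarizeArchitecture()]) and the weight
#' tree: per-stage 3x3x3 conv stacks, per-stage 1x1x1 score convolutions,
#' and the final 1x1x1 fuse convolution. Trilinear upsampling layers are
#' fixed (non-learning) and therefore carry no weights.
#'
#' @slot config a [NetConfig].
#' @slot layers list of layer descriptors in forward order.
#' @slot weights nested list of numeric arrays.
#' @export
setClass("Network",
  representation(config = "NetConfig", layers = "list", weights = "list"))

#' TrainConfig: optimisation hyperparameters
#'
#' Defaults are the production settings: learning rate 1e-2, Nesterov
#' momentum 0.9, EMA decay 0.999, global gradient-norm clip 4, batch size 1.
#' \code{steps} defaults to 30000 and is overridden for desk-scale runs.
#'
#' @slot learningRate,momentum,emaDecay,clipNorm,steps,batchSize,seed
#'   numeric/integer scalars; see Details.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", momentum = "numeric",
                 emaDecay = "numeric", clipNorm = "numeric",
                 steps = "integer", batchSize = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1) msg <- c(msg, "momentum must be in [0,1)")
  if (object@emaDecay <= 0 || object@emaDecay >= 1) msg <- c(msg, "emaDecay must be in (0,1)")
  if (object@clipNorm <= 0) msg <- c(msg, "clipNorm must be > 0")
  if (object@steps < 0) msg <- c(msg, "steps must be >= 0")
  if (object@batchSize != 1L) msg <- c(msg, "batchSize = 1 is the only supported value")
  if (length(msg)) msg else TRUE
})

#' TrainState: result of a training run
#'
#' Holds the trained current weights, the exponential-moving-average weights
#' used for inference, the step counter and the per-step loss history.
#'
#' @slot network the [Network] with final current weights.
#' @slot emaWeights nested list mirroring the network weights.
#' @slot step integer steps completed.
#' @slot lossHistory data.frame(step, cohort, loss).
#' @slot config the [TrainConfig] used.
#' @export
setClass("TrainState",
  representation(network = "Network", emaWeights = "list", step = "integer",
                 lossHistory = "data.frame", config = "TrainConfig"))

#' EvalReport: per-image and aggregated segmentation metrics
#'
#' @slot perImage data.frame with one row per evaluated pair: subject,
#'   cohort, timepoint, dsc, hdMM, fnPct, fpPct, volDiffPct.
#' @slot summary data.frame of cohort-stratified and overall aggregates
#'   (median/mean/SD per metric); \code{sdDefined} flags groups of size 1,
#'   whose SD is reported as 0.
#' @export
setClass("EvalReport",
  representation(perImage = "data.frame", summary = "data.frame"))

#' LongitudinalReport: same-subject volume consistency
#'
#' @slot perSubject data.frame: subject, nTimepoints, minVolCm3, maxVolCm3,
#'   maxDiffCm3 (max - min over all scans of the subject).
#' @slot medianMaxDiffCm3 median of maxDiffCm3 across subjects.
#' @export
setClass("LongitudinalReport",
  representation(perSubject = "data.frame", medianMaxDiffCm3 = "numeric"))

#' ExperimentPlan: layout of a cohort-diversity experiment
#'
#' @slot levels integer vector of cohort-count levels.
#' @slot trainingsPerLevel integer, trainings at each level below the full set.
#' @slot coverage logical, require every cohort in >= 1 subset per level.
#' @slot trainConfig shared [TrainConfig]; @slot netSeed integer;
#' @slot masterSeed integer driving subset selection and per-training seeds.
#' @export
setClass("ExperimentPlan",
  representation(levels = "integer", trainingsPerLevel = "integer",
                 coverage = "logical", trainConfig = "TrainConfig",
                 netSeed = "integer", masterSeed = "integer"))
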