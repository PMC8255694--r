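# Synthetic multi-cohort head phantoms with analytic ICC ground truth.
#
# Geometry is a nest of confocal-offset ellipsoidal shells: a brain core,
# a CSF rim out to a dura-like boundary (together the ICC), a dark skull
# shell and a bright scalp shell.  The true ICC volume is the closed-form
# ellipsoid volume, so longitudinal consistency can be tested against an
# analytic reference.  On T1-weighted contrast the CSF rim is darkest and
# the skull/dura band sits above it, so the ICC boundary is a visible
# intensity step, as it is in real scans.

#' Construct a synthetic cohort specification
#'
#' @param cohortId short identifier, unique within a dataset.
#' @param nSubjects subjects in the cohort.
#' @param nTimepoints scans per subject; subjects keep one fixed geometry
#'   across timepoints, so a series shares one true ICC volume.
#' @param tissueMeans named mean intensities for background, scalp, skull,
#'   csf and brain (arbitrary units; defaults emulate T1-weighted contrast
#'   with CSF darkest and scalp brightest).
#' @param noiseSigma additive Gaussian noise SD in intensity units.
#' @param biasAmplitude peak fractional deviation of the smooth
#'   multiplicative bias field, in [0, 1].
#' @param radiiMin,radiiMax per-axis ICC semi-axis range in mm.
#' @param maxRotDeg,maxTransMm per-timepoint rigid pose range.
#' @param voxelSpacing per-axis voxel size in mm.
#' @param dims lattice dimensions.
#' @param seed integer; together with the other fields it fully determines
#'   the cohort's data stream.
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec("A", nSubjects = 2, dims = c(32, 32, 32),
#'                    radiiMin = c(15, 15, 14), radiiMax = c(19, 19, 18))
#' vm <- synthHead(spec, 1)
#' @export
cohortSpec <- function(cohortId, nSubjects = 10L, nTimepoints = 1L,
                       tissueMeans = c(background = 0, scalp = 90, skull = 35,
                                       csf = 15, brain = 70),
                       noiseSigma = 5, biasAmplitude = 0.2,
                       radiiMin = c(38, 40, 36), radiiMax = c(44, 46, 42),
                       maxRotDeg = 5, maxTransMm = 2,
                       voxelSpacing = c(2, 2, 2), dims = c(64L, 64L, 64L),
                       seed = 1L) {
  new("CohortSpec", cohortId = as.character(cohortId),
      nSubjects = as.integer(nSubjects), nTimepoints = as.integer(nTimepoints),
      tissueMeans = tissueMeans, noiseSigma = noiseSigma,
      biasAmplitude = biasAmplitude, radiiMin = as.numeric(radiiMin),
      radiiMax = as.numeric(radiiMax), maxRotDeg = maxRotDeg,
      maxTransMm = maxTransMm, voxelSpacing = as.numeric(voxelSpacing),
      dims = as.integer(dims), seed = as.integer(seed))
}

# Shell thicknesses scale with head size so one geometry model serves both
# full-size and desk-scale lattices.
shellFractions <- c(csf = 0.08, skull = 0.12, scalp = 0.14)

#' Per-subject phantom geometry
#'
#' Draws the fixed geometry of one subject: ICC semi-axes uniform in the
#' cohort's per-axis range and shell thicknesses proportional to head size
#' with a small per-subject jitter. The geometry (and hence the analytic
#' true ICC volume) depends only on (spec seed, subject), never on the
#' timepoint, so longitudinal series share it exactly.
#'
#' @param spec a [CohortSpec-class]. @param subjectIndex 1-based subject index.
#' @return list with iccSemiAxes (mm), csfThickness, skullThickness,
#'   scalpThickness (mm) and trueIccVolumeCm3 = 4/3 pi abc / 1000.
#' @export
subjectGeometry <- function(spec, subjectIndex) {
  stopifnot(subjectIndex >= 1, subjectIndex <= spec@nSubjects)
  withSeed(mixSeed(spec@seed, subjectIndex), {
    a <- runif(3, spec@radiiMin, spec@radiiMax)
    abar <- mean(a)
    th <- shellFractions * abar * runif(3, 0.85, 1.15)
    list(iccSemiAxes = a,
         csfThickness = unname(th["csf"]),
         skullThickness = unname(th["skull"]),
         scalpThickness = unname(th["scalp"]),
         trueIccVolumeCm3 = 4 / 3 * pi * prod(a) / 1000)
  })
}

# Voxel-centre coordinates (mm), lattice centred on the origin: V x 3 matrix.
voxelGrid <- function(dims, spacing) {
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - (dims[k] + 1) / 2)) * spacing[k])
  cbind(rep(ax[[1]], times = dims[2] * dims[3]),
        rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
        rep(ax[[3]], each = dims[1] * dims[2]))
}

rotationMatrix <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Squared ellipsoidal radius of body-frame coordinates U (V x 3).
ellipsoidRho2 <- function(U, semiAxes) {
  (U[, 1] / semiAxes[1])^2 + (U[, 2] / semiAxes[2])^2 + (U[, 3] / semiAxes[3])^2
}

#' Synthesize one whole-head phantom scan
#'
#' Generates a [HeadVolume-class]/[ICCMask-class] pair for one subject and
#' timepoint. The subject's geometry is fixed; the timepoint adds a rigid
#' pose (applied analytically: region membership is evaluated at rigidly
#' transformed voxel-centre coordinates, so the mask is exactly the
#' voxelization of the posed geometry), a smooth quadratic multiplicative
#' bias field, and additive Gaussian noise. Generation is a pure function of
#' (spec seed, subjectIndex, timepoint).
#'
#' @param spec a [CohortSpec-class].
#' @param subjectIndex 1-based subject index (<= nSubjects).
#' @param timepoint 1-based scan index.
#' @return list(volume = HeadVolume, mask = ICCMask).
#' @export
synthHead <- function(spec, subjectIndex, timepoint = 1L) {
  validObject(spec)
  if (subjectIndex < 1 || subjectIndex > spec@nSubjects)
    stop("subjectIndex must be in 1..nSubjects")
  if (timepoint < 1) stop("timepoint must be >= 1")
  geom <- subjectGeometry(spec, subjectIndex)
  dims <- spec@dims
  sp <- spec@voxelSpacing
  halfExtent <- dims * sp / 2
  outer <- geom$iccSemiAxes + geom$skullThickness + geom$scalpThickness
  if (any(outer + spec@maxTransMm >= halfExtent))
    stop(sprintf("head (outer semi-axes %s mm + translation %g mm) does not fit the %s lattice",
                 paste(signif(outer, 4), collapse = "x"), spec@maxTransMm,
                 paste(dims, collapse = "x")))

  withSeed(mixSeed(spec@seed, subjectIndex, timepoint, 7L), {
    angles <- runif(3, -spec@maxRotDeg, spec@maxRotDeg)
    trans <- runif(3, -spec@maxTransMm, spec@maxTransMm)
    biasCoef <- rnorm(9)
    noise <- if (spec@noiseSigma > 0) rnorm(prod(dims), 0, spec@noiseSigma) else 0
  })

  X <- voxelGrid(dims, sp)
  R <- rotationMatrix(angles)
  U <- sweep(X, 2, trans) %*% R  # = t(R) applied to rows

  a <- geom$iccSemiAxes
  inIcc <- ellipsoidRho2(U, a) <= 1
  inBrain <- ellipsoidRho2(U, pmax(a - geom$csfThickness, 0.1)) <= 1
  inSkull <- ellipsoidRho2(U, a + geom$skullThickness) <= 1
  inScalp <- ellipsoidRho2(U, a + geom$skullThickness + geom$scalpThickness) <= 1

  tm <- spec@tissueMeans
  intens <- rep(tm[["background"]], prod(dims))
  intens[inScalp] <- tm[["scalp"]]
  intens[inSkull] <- tm[["skull"]]
  intens[inIcc] <- tm[["csf"]]
  intens[inBrain] <- tm[["brain"]]

  if (spec@biasAmplitude > 0) {
    u <- sweep(X, 2, halfExtent, "/")  # normalized to [-1, 1]
    M <- cbind(u, u^2, u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3])
    field <- as.numeric(M %*% biasCoef)
    field <- field - mean(field)
    field <- field / max(abs(field))
    intens <- intens * (1 + spec@biasAmplitude * field)
  }
  intens <- intens + noise

  vol <- new("HeadVolume", voxels = array(intens, dims), spacing = sp,
             subjectId = sprintf("%s_s%03d", spec@cohortId, subjectIndex),
             cohortId = spec@cohortId, timepoint = as.integer(timepoint))
  mask <- new("ICCMask", voxels = array(as.integer(inIcc), dims), spacing = sp,
              subjectId = vol@subjectId, cohortId = spec@cohortId,
              timepoint = as.integer(timepoint))
  list(volume = vol, mask = mask)
}

#' Synthesize a longitudinal series for one subject
#'
#' All timepoints share one subject geometry (identical analytic ICC
#' volume); they differ only in rigid pose, bias field and noise
#' realization.
#'
#' @inheritParams synthHead
#' @param nTimepoints number of serial scans, >= 2.
#' @return list of list(volume, mask), one per timepoint.
#' @export
synthLongitudinal <- function(spec, subjectIndex, nTimepoints) {
  if (nTimepoints < 2) stop("nTimepoints must be >= 2 for a longitudinal series")
  lapply(seq_len(nTimepoints), function(t) synthHead(spec, subjectIndex, t))
}

# Largest-remainder apportionment of n subjects over split fractions.
splitCounts <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order <- order(raw - base, decreasing = TRUE)
    base[order[seq_len(rem)]] <- base[order[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a multi-cohort dataset on disk
#'
#' Writes NIfTI-1 volume/mask pairs for every subject and timepoint of the
#' given cohorts, assigns train/eval/test splits at the subject level (every
#' scan of a subject lands in exactly one split), and writes a tab-separated
#' manifest plus a TOML sidecar echoing the generation parameters.
#'
#' @param specs list of [CohortSpec-class] with distinct cohort ids.
#' @param splitFractions named numeric(3) (train, eval, test) summing to 1.
#'   Subject counts per split use largest-remainder rounding.
#' @param seed integer seed for the split assignment.
#' @param outDir output directory (created if needed).
#' @return the manifest data.frame (also written to
#'   \code{file.path(outDir, "manifest.tsv")}).
#' @export
synthDataset <- function(specs, splitFractions = c(train = 0.8, eval = 0.1, test = 0.1),
                         seed = 1L, outDir = tempfile("synthdata")) {
  ids <- vapply(specs, function(s) s@cohortId, character(1))
  if (anyDuplicated(ids)) stop("duplicate cohort_id in specs")
  if (abs(sum(splitFractions) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (length(splitFractions) != 3L) stop("splitFractions must have 3 entries (train, eval, test)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  splitNames <- c("train", "eval", "test")
  rows <- list()
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    counts <- splitCounts(spec@nSubjects, as.numeric(splitFractions))
    perm <- withSeed(mixSeed(seed, ci, 13L), sample.int(spec@nSubjects))
    splitOf <- rep(splitNames, counts)[order(perm)]
    for (si in seq_len(spec@nSubjects)) {
      for (t in seq_len(spec@nTimepoints)) {
        pair <- synthHead(spec, si, t)
        stem <- sprintf("%s_s%03d_t%02d", spec@cohortId, si, t)
        imgPath <- file.path(outDir, paste0(stem, "_img.nii.gz"))
        maskPath <- file.path(outDir, paste0(stem, "_mask.nii.gz"))
        writeVolume(pair$volume, imgPath)
        writeMask(pair$mask, maskPath)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = pair$volume@subjectId, cohort_id = spec@cohortId,
          timepoint = t, split = splitOf[si],
          image_path = imgPath, mask_path = maskPath,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.tsv"))
  sidecar <- list(seed = seed,
                  split_fractions = as.numeric(splitFractions),
                  cohorts = lapply(specs, function(s) list(
                    cohort_id = s@cohortId, n_subjects = s@nSubjects,
                    n_timepoints = s@nTimepoints, noise_sigma = s@noiseSigma,
                    bias_amplitude = s@biasAmplitude, seed = s@seed,
                    dims = s@dims, voxel_spacing = s@voxelSpacing,
                    radii_min = s@radiiMin, radii_max = s@radiiMax,
                    max_rot_deg = s@maxRotDeg, max_trans_mm = s@maxTransMm)))
  writeTOML(sidecar, file.path(outDir, "params.toml"))
  manifest
}
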