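# Shared fixtures: all synthetic, built in code at test time.

# A tiny cohort whose heads fit a 16^3 lattice at 2 mm (desk micro scale).
tinySpec <- function(id = "T", nSubjects = 4L, seed = 11L, nTimepoints = 1L,
                     noiseSigma = 3, biasAmplitude = 0.1,
                     maxRotDeg = 4, maxTransMm = 1) {
  cohortSpec(id, nSubjects = nSubjects, nTimepoints = nTimepoints,
             noiseSigma = noiseSigma, biasAmplitude = biasAmplitude,
             radiiMin = c(7, 7.5, 6.5), radiiMax = c(9, 9.5, 8.5),
             maxRotDeg = maxRotDeg, maxTransMm = maxTransMm,
             voxelSpacing = c(2, 2, 2), dims = c(16L, 16L, 16L), seed = seed)
}

# Build an ICCMask from a plain array.
mask3d <- function(arr, spacing = c(1, 1, 1), subject = "s", cohort = "c",
                   timepoint = 1L) {
  new("ICCMask", voxels = array(as.integer(arr), dim(arr)),
      spacing = spacing, subjectId = subject, cohortId = cohort,
      timepoint = as.integer(timepoint))
}

# Random mask on a small lattice with at least one voxel set.
randomMask <- function(dims, p = 0.2, spacing = c(1, 1, 1)) {
  m <- array(as.integer(runif(prod(dims)) < p), dims)
  if (sum(m) == 0) m[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- 1L
  mask3d(m, spacing)
}

# Brute-force double-loop Hausdorff oracle in mm (independent of the
# distance-transform implementation).
bruteHausdorff <- function(A, B) {
  sp <- A@spacing
  ia <- which(A@voxels == 1L, arr.ind = TRUE)
  ib <- which(B@voxels == 1L, arr.ind = TRUE)
  directed <- function(P, Q) {
    max(apply(P, 1, function(p) {
      min(sqrt(colSums((t(Q) - p)^2 * sp^2)))
    }))
  }
  max(directed(ia, ib), directed(ib, ia))
}

# Four contrast-heterogeneous cohorts on the 16^3 micro lattice, mirroring
# the desk cohorts' tissue/noise/bias profiles at micro scale.
microCohortSpecs <- function(seed, nSubjects = 12L) {
  base <- c(background = 0, scalp = 90, skull = 35, csf = 15, brain = 70)
  prof <- list(A = list(tm = base,        ns = 4, ba = 0.10),
               B = list(tm = base * 0.75, ns = 6, ba = 0.20),
               C = list(tm = base * 1.25, ns = 8, ba = 0.15),
               D = list(tm = c(background = 0, scalp = 100, skull = 45,
                               csf = 20, brain = 60), ns = 5, ba = 0.30))
  lapply(names(prof), function(k)
    cohortSpec(k, nSubjects = nSubjects, tissueMeans = prof[[k]]$tm,
               noiseSigma = prof[[k]]$ns, biasAmplitude = prof[[k]]$ba,
               radiiMin = c(7, 7.5, 6.5), radiiMax = c(9, 9.5, 8.5),
               maxRotDeg = 4, maxTransMm = 1, voxelSpacing = c(2, 2, 2),
               dims = c(16L, 16L, 16L), seed = seed + match(k, names(prof))))
}

# A two-cohort micro manifest on disk for training plumbing tests.
microManifest <- function(dir = tempfile("micro"), nSubjects = 3L,
                          nTimepoints = 1L, seed = 7L) {
  specs <- list(tinySpec("T1", nSubjects, seed = mixSeedT(seed, 1),
                         nTimepoints = nTimepoints),
                tinySpec("T2", nSubjects, seed = mixSeedT(seed, 2),
                         nTimepoints = nTimepoints))
  synthDataset(specs, c(train = 2 / 3, eval = 0, test = 1 / 3),
               seed = seed, outDir = dir)
}

# Local seed folding for fixtures (mirrors the package's derivation rule).
mixSeedT <- function(...) {
  parts <- abs(as.numeric(c(...)))
  s <- 104729
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}
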