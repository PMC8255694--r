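test_that("phantom generation is a pure function of (seed, subject, timepoint)", {
  spec <- tinySpec(seed = 42L)
  a <- synthHead(spec, 2, 1)
  b <- synthHead(spec, 2, 1)
  expect_identical(a$volume@voxels, b$volume@voxels)
  expect_identical(a$mask@voxels, b$mask@voxels)
  # different timepoints share geometry but differ in realization
  c2 <- synthHead(spec, 2, 2)
  expect_false(identical(a$volume@voxels, c2$volume@voxels))
  expect_identical(subjectGeometry(spec, 2), subjectGeometry(spec, 2))
})

test_that("noise-free, bias-free phantoms are piecewise constant at tissue means", {
  spec <- tinySpec(noiseSigma = 0, biasAmplitude = 0)
  v <- synthHead(spec, 1)$volume@voxels
  expect_true(all(v %in% spec@tissueMeans))
  # all five tissue classes should actually appear
  expect_setequal(sort(unique(as.numeric(v))), sort(unname(spec@tissueMeans)))
})

test_that("ground-truth masks are invariant to noise and bias settings", {
  s1 <- tinySpec(noiseSigma = 0, biasAmplitude = 0)
  s2 <- tinySpec(noiseSigma = 0, biasAmplitude = 0.9)
  s3 <- tinySpec(noiseSigma = 9, biasAmplitude = 0)
  p1 <- synthHead(s1, 1); p2 <- synthHead(s2, 1); p3 <- synthHead(s3, 1)
  expect_identical(p1$mask@voxels, p2$mask@voxels)
  expect_identical(p1$mask@voxels, p3$mask@voxels)
  expect_false(identical(p1$volume@voxels, p2$volume@voxels))
})

test_that("masks are single 6-connected components matching the analytic geometry", {
  label6 <- getFromNamespace("cpp_label6", "iccseg")
  for (s in 1:3) {
    pm <- synthHead(tinySpec(seed = 100L + s), 1)
    expect_equal(max(label6(pm$mask@voxels)), 1L)
  }
})

test_that("voxelized volume approaches the analytic ICC volume as spacing shrinks", {
  mk <- function(dims, sp) cohortSpec("Z", nSubjects = 2, dims = dims,
                                      voxelSpacing = sp,
                                      radiiMin = c(15, 16, 14),
                                      radiiMax = c(19, 20, 18), seed = 9L)
  for (i in 1:2) {
    tv <- subjectGeometry(mk(c(32L, 32L, 32L), c(2, 2, 2)), i)$trueIccVolumeCm3
    e2 <- abs(maskVolumeCm3(synthHead(mk(c(32L, 32L, 32L), c(2, 2, 2)), i)$mask) - tv) / tv
    e1 <- abs(maskVolumeCm3(synthHead(mk(c(64L, 64L, 64L), c(1, 1, 1)), i)$mask) - tv) / tv
    expect_lt(e1, e2)
    expect_lt(e2, 0.01)
  }
})

test_that("longitudinal series share one geometry and nearly constant mask volume", {
  expect_error(synthLongitudinal(tinySpec(), 1, 1), "2")
  # zero pose range: only intensities vary, masks bit-identical
  s0 <- tinySpec(maxRotDeg = 0, maxTransMm = 0)
  ser0 <- synthLongitudinal(s0, 1, 3)
  expect_identical(ser0[[1]]$mask@voxels, ser0[[2]]$mask@voxels)
  expect_identical(ser0[[2]]$mask@voxels, ser0[[3]]$mask@voxels)
  expect_false(identical(ser0[[1]]$volume@voxels, ser0[[2]]$volume@voxels))
  # at the generator's default lattice the voxelization jitter is < 1% of
  # the analytic volume for rotations <= 5 degrees
  for (k in 1:5) {
    sp <- cohortSpec(sprintf("L%d", k), nSubjects = 1, seed = 200L + k)
    ser <- synthLongitudinal(sp, 1, 3)
    vols <- vapply(ser, function(p) maskVolumeCm3(p$mask), numeric(1))
    tv <- subjectGeometry(sp, 1)$trueIccVolumeCm3
    expect_lt((max(vols) - min(vols)) / tv, 0.01)
  }
})

test_that("degenerate geometry and index preconditions error loudly", {
  big <- cohortSpec("B", nSubjects = 1, dims = c(16L, 16L, 16L),
                    radiiMin = c(15, 15, 15), radiiMax = c(16, 16, 16), seed = 1L)
  expect_error(synthHead(big, 1), "does not fit")
  spec <- tinySpec()
  expect_error(synthHead(spec, 0), "subjectIndex")
  expect_error(synthHead(spec, spec@nSubjects + 1L), "subjectIndex")
})

test_that("dataset manifests split subjects disjointly with documented rounding", {
  dir <- tempfile("ds")
  spec <- tinySpec("A", nSubjects = 10L, seed = 3L)
  man <- synthDataset(list(spec), c(train = 0.8, eval = 0.1, test = 0.1),
                      seed = 5L, outDir = dir)
  counts <- table(man$split[!duplicated(man$subject_id)])
  expect_equal(unname(counts[c("train", "eval", "test")]), c(8L, 1L, 1L),
               ignore_attr = TRUE)
  expect_true(all(table(man$subject_id, man$split) %in% c(0L, 1L)))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "params.toml")))

  # all timepoints of a subject carry one split label
  dir2 <- tempfile("ds2")
  man2 <- synthDataset(list(tinySpec("A", nSubjects = 4L, nTimepoints = 3L)),
                       c(train = 0.5, eval = 0.25, test = 0.25),
                       seed = 5L, outDir = dir2)
  perSubj <- tapply(man2$split, man2$subject_id, function(s) length(unique(s)))
  expect_true(all(perSubj == 1L))
  expect_equal(sum(man2$subject_id == man2$subject_id[1]), 3L)

  # same seed twice reproduces the manifest (paths aside)
  man3 <- synthDataset(list(tinySpec("A", nSubjects = 4L, nTimepoints = 3L)),
                       c(train = 0.5, eval = 0.25, test = 0.25),
                       seed = 5L, outDir = tempfile("ds3"))
  expect_identical(man2[c("subject_id", "cohort_id", "timepoint", "split")],
                   man3[c("subject_id", "cohort_id", "timepoint", "split")])

  expect_error(synthDataset(list(tinySpec("A"), tinySpec("A")), seed = 1L),
               "duplicate")
  expect_error(synthDataset(list(tinySpec("A")), c(0.5, 0.2, 0.2), seed = 1L),
               "sum to 1")
})
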