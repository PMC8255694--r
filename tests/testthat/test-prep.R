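test_that("NIfTI volumes and masks round-trip through disk", {
  pm <- synthHead(tinySpec(seed = 21L), 1)
  f1 <- tempfile(fileext = ".nii.gz")
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(pm$volume, f1)
  writeMask(pm$mask, f2)
  v <- readVolume(f1)
  m <- readMask(f2)
  expect_identical(dim(v@voxels), dim(pm$volume@voxels))
  expect_equal(v@spacing, pm$volume@spacing)
  expect_identical(v@voxels, pm$volume@voxels)     # written as doubles
  expect_identical(m@voxels, pm$mask@voxels)       # bit-exact for masks
})

test_that("I/O rejects 4D images, missing files and non-binary masks", {
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(readVolume(f4), "3D")
  expect_error(readVolume(tempfile()), "no such file")
  fm <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(c(0, 1, 2), c(3, 3, 3))), fm)
  expect_error(readMask(fm), "outside \\{0, 1\\}")
})

test_that("autocrop finds the head bounding box and inverts exactly", {
  spec <- tinySpec(seed = 33L)
  pm <- synthHead(spec, 1)
  # embed the 16^3 head in a large zero background
  big <- array(0, c(40L, 40L, 40L))
  big[9:24, 11:26, 5:20] <- pm$volume@voxels
  vol <- new("HeadVolume", voxels = big, spacing = c(2, 2, 2))
  cr <- autocrop(vol, margin = 2L)
  # head voxels (mask region) must be inside the crop, with about margin slack
  headIdx <- which(big > 0.5 * max(big), arr.ind = TRUE)
  lo <- apply(headIdx, 2, min); hi <- apply(headIdx, 2, max)
  expect_true(all(cr$cropStart + 1L <= lo))
  expect_true(all(cr$cropStop >= hi))
  expect_true(all(cr$cropStart + 1L >= lo - 4L))
  expect_true(all(cr$cropStop <= hi + 4L))
  # restore: re-embedding the crop recovers the original within the box
  rec <- preprocess(vol, 3)$record
  expect_identical(as.integer(dim(big)), rec@nativeDims)

  # already-tight noise-free volume is unchanged with a zero-offset record
  clean <- synthHead(tinySpec(seed = 33L, noiseSigma = 0, biasAmplitude = 0), 1)
  crClean <- autocrop(clean$volume, margin = 2L)
  cr2 <- autocrop(crClean$volume, margin = 2L)
  expect_identical(dim(cr2$volume@voxels), dim(crClean$volume@voxels))
  expect_identical(cr2$cropStart, c(0L, 0L, 0L))

  expect_error(autocrop(new("HeadVolume", voxels = array(0, c(8, 8, 8)),
                            spacing = c(1, 1, 1))), "background")
})

test_that("intensity normalization hits zero mean, unit SD and errors on constants", {
  v01 <- new("HeadVolume", voxels = array(rep(c(0, 2), 32), c(4, 4, 4)),
             spacing = c(1, 1, 1))
  nm <- normalizeIntensity(v01)
  expect_setequal(unique(as.numeric(nm$volume@voxels)), c(-1, 1))
  pm <- synthHead(tinySpec(seed = 5L), 1)
  cr <- autocrop(pm$volume)
  nm2 <- normalizeIntensity(cr$volume)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_lt(abs(mean(nm2$volume@voxels)), 1e-6)
  expect_lt(abs(popSd(as.numeric(nm2$volume@voxels)) - 1), 1e-6)
  expect_error(normalizeIntensity(new("HeadVolume", voxels = array(3, c(4, 4, 4)),
                                      spacing = c(1, 1, 1))), "constant")
})

test_that("padding reaches the next multiple of 2^(N-1), centred", {
  mk <- function(d) new("HeadVolume", voxels = array(rnorm(prod(d)), d),
                        spacing = c(1, 1, 1))
  pd <- padToStageMultiple(mk(c(91L, 109L, 91L)), 5)
  expect_identical(dim(pd$volume@voxels), c(96L, 112L, 96L))
  expect_identical(pd$padBefore + pd$padAfter, c(5L, 3L, 5L))
  expect_true(all(pd$padAfter - pd$padBefore %in% c(0L, 1L)))
  pd2 <- padToStageMultiple(mk(c(96L, 96L, 96L)), 5)
  expect_identical(dim(pd2$volume@voxels), c(96L, 96L, 96L))
  expect_identical(pd2$padBefore, c(0L, 0L, 0L))
  pd3 <- padToStageMultiple(mk(c(7L, 7L, 7L)), 2)
  expect_identical(dim(pd3$volume@voxels), c(8L, 8L, 8L))
  expect_error(padToStageMultiple(mk(c(8L, 8L, 8L)), 6), "nStages")
})

test_that("preprocess composes crop, normalize, pad in order and inverts", {
  prepMaskArray <- getFromNamespace("prepMaskArray", "iccseg")
  for (N in c(2, 3, 5)) {
    pm <- synthHead(tinySpec(seed = 40L + N), 1)
    pp <- preprocess(pm$volume, N)
    d <- dim(pp$volume@voxels)
    expect_true(all(d %% 2^(N - 1) == 0))
    # normalization statistics were computed before padding: the mean over
    # the non-pad region is 0 even though padded voxels are 0
    rec <- pp$record
    b <- rec@padBefore
    cd <- rec@cropStop - rec@cropStart
    inner <- pp$volume@voxels[b[1] + seq_len(cd[1]), b[2] + seq_len(cd[2]),
                              b[3] + seq_len(cd[3])]
    expect_lt(abs(mean(inner)), 1e-6)
    expect_lt(abs(sqrt(mean((inner - mean(inner))^2)) - 1), 1e-6)
    # determinism
    pp2 <- preprocess(pm$volume, N)
    expect_identical(pp$volume@voxels, pp2$volume@voxels)
    # mask round trip: restore(prep(mask)) == mask (crop box covers the head)
    gtPrep <- prepMaskArray(pm$mask@voxels, rec)
    back <- restoreNative(gtPrep, rec)
    expect_identical(array(as.integer(back), dim(back)), pm$mask@voxels)
    # intensity round trip within the crop box (de-normalized)
    restored <- restoreNative(pp$volume@voxels, rec) * rec@normSd + rec@normMean
    lo <- rec@cropStart
    inside <- restored[lo[1] + seq_len(cd[1]), lo[2] + seq_len(cd[2]),
                       lo[3] + seq_len(cd[3])]
    orig <- pm$volume@voxels[lo[1] + seq_len(cd[1]), lo[2] + seq_len(cd[2]),
                             lo[3] + seq_len(cd[3])]
    expect_equal(inside, orig, tolerance = 1e-12)
  }
})

test_that("restoreNative fills outside-crop with zero and validates dims", {
  pm <- synthHead(tinySpec(seed = 50L), 1)
  big <- array(0, c(24L, 24L, 24L))
  big[5:20, 5:20, 5:20] <- pm$volume@voxels
  vol <- new("HeadVolume", voxels = big, spacing = c(2, 2, 2))
  pp <- preprocess(vol, 2)
  ones <- array(1, dim(pp$volume@voxels))
  back <- restoreNative(ones, pp$record)
  rec <- pp$record
  cd <- rec@cropStop - rec@cropStart
  expect_equal(sum(back), prod(cd))
  expect_true(all(back %in% c(0, 1)))
  expect_error(restoreNative(array(1, c(3, 3, 3)), pp$record), "match")
})
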