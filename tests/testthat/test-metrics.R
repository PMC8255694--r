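test_that("Dice matches hand values and is symmetric", {
  d <- c(4L, 4L, 4L)
  A <- array(0L, d); A[1:2, 1:2, 1:2] <- 1L          # 8 voxels
  B <- A
  expect_equal(dice(mask3d(A), mask3d(B)), 1.0)
  C <- array(0L, d); C[3:4, 3:4, 3:4] <- 1L          # disjoint 8 voxels
  expect_equal(dice(mask3d(A), mask3d(C)), 0.0)
  D <- array(0L, d); D[1:2, 1:2, 1] <- 1L; D[3:4, 3:4, 4] <- 1L  # |D|=8, overlap 4
  expect_equal(dice(mask3d(A), mask3d(D)), 0.5)
  expect_equal(dice(mask3d(D), mask3d(A)), 0.5)
  expect_error(dice(mask3d(array(0L, d)), mask3d(array(0L, d))), "empty")
  expect_error(dice(mask3d(A), mask3d(array(0L, c(3, 3, 3)))), "dimensions")
})

test_that("Hausdorff distance matches hand values and scales with spacing", {
  d <- c(8L, 8L, 8L)
  A <- array(0L, d); A[2, 2, 2] <- 1L
  B <- array(0L, d); B[5, 6, 2] <- 1L               # offset (3,4,0): 3-4-5
  expect_equal(hausdorffMM(mask3d(A), mask3d(B)), 5.0)
  expect_equal(hausdorffMM(mask3d(A), mask3d(A)), 0.0)
  # doubling spacing doubles the distance on the same index masks
  expect_equal(hausdorffMM(mask3d(A, spacing = c(2, 2, 2)),
                           mask3d(B, spacing = c(2, 2, 2))), 10.0)
  expect_error(hausdorffMM(mask3d(A), mask3d(array(0L, d))), "empty")
})

test_that("distance-transform Hausdorff equals the brute-force double loop", {
  set.seed(77)
  for (trial in 1:8) {
    dims <- sample(4:12, 3, replace = TRUE)
    sp <- sample(c(1, 1, 2, 0.5), 3, replace = TRUE)
    A <- randomMask(dims, p = 0.15, spacing = sp)
    B <- randomMask(dims, p = 0.15, spacing = sp)
    expect_equal(hausdorffMM(A, B), bruteHausdorff(A, B), tolerance = 1e-9)
    # symmetry
    expect_equal(hausdorffMM(A, B), hausdorffMM(B, A))
  }
})

test_that("FN/FP/volume-difference percentages match their definitions", {
  d <- c(5L, 5L, 5L)
  gt <- array(0L, d); gt[1:4, 1:5, 1:5] <- 1L       # 100 voxels
  pred <- gt
  expect_equal(falseNegativePct(mask3d(pred), mask3d(gt)), 0)
  expect_equal(falsePositivePct(mask3d(pred), mask3d(gt)), 0)
  miss2 <- gt; miss2[1, 1, 1:2] <- 0L               # misses 2 of 100
  expect_equal(falseNegativePct(mask3d(miss2), mask3d(gt)), 2.0)
  expect_equal(falseNegativePct(mask3d(array(0L, d)), mask3d(gt)), 100)
  # pred = gt minus 3 + 3 outside: |pred| = 100, 3 outside gt
  pred3 <- gt; pred3[1, 1, 1:3] <- 0L; pred3[5, 5, 1:3] <- 1L
  expect_equal(falsePositivePct(mask3d(pred3), mask3d(gt)), 3.0)
  expect_equal(falsePositivePct(mask3d(miss2), mask3d(gt)), 0)  # subset of gt
  expect_error(falsePositivePct(mask3d(array(0L, d)), mask3d(gt)), "empty")

  # volume difference on 10 mm voxels: 1 voxel = 1 cm^3
  gtv <- array(1L, c(10L, 10L, 10L))                 # 1000 cm^3
  expect_equal(volumeDiffPct(mask3d(gtv, spacing = c(10, 10, 10)),
                             mask3d(gtv, spacing = c(10, 10, 10))), 0)
  # explicit +1% and -5% cases
  d2 <- c(10L, 10L, 11L)
  p1 <- array(0L, d2); p1[seq_len(1010)] <- 1L
  g1 <- array(0L, d2); g1[seq_len(1000)] <- 1L
  expect_equal(volumeDiffPct(mask3d(p1, spacing = c(10, 10, 10)),
                             mask3d(g1, spacing = c(10, 10, 10))), 1.0)
  p2 <- array(0L, d2); p2[seq_len(950)] <- 1L
  expect_equal(volumeDiffPct(mask3d(p2, spacing = c(10, 10, 10)),
                             mask3d(g1, spacing = c(10, 10, 10))), -5.0)
})

test_that("DSC, FN and FP derive consistently from one intersection count", {
  set.seed(55)
  for (trial in 1:6) {
    pred <- randomMask(c(7, 7, 7), 0.3)
    gt <- randomMask(c(7, 7, 7), 0.3)
    i <- sum(pred@voxels * gt@voxels)
    p <- sum(pred@voxels); g <- sum(gt@voxels)
    expect_equal(dice(pred, gt), 2 * i / (p + g))
    expect_equal(falseNegativePct(pred, gt), 100 * (g - i) / g)
    expect_equal(falsePositivePct(pred, gt), 100 * (p - i) / p)
  }
})

test_that("longitudinal report computes per-subject max minus min volume", {
  mk <- function(n) mask3d(array(c(rep(1L, n), rep(0L, 12^3 - n)), c(12, 12, 12)),
                           spacing = c(10, 10, 10))  # n cm^3
  rep1 <- longitudinalMaxDiff(list(s1 = list(mk(1400), mk(1404), mk(1398)),
                                   s2 = list(mk(500), mk(500))))
  expect_equal(rep1@perSubject$maxDiffCm3, c(6, 0))
  expect_equal(rep1@medianMaxDiffCm3, 3)
  expect_error(longitudinalMaxDiff(list(s1 = list(mk(10)))), "fewer than 2")
})

test_that("evaluation reports aggregate per cohort and recompute from rows", {
  d <- c(6L, 6L, 6L)
  mkPair <- function(overlap, total = 10L) {
    gt <- array(0L, d); gt[seq_len(total)] <- 1L
    pred <- array(0L, d); pred[seq_len(overlap)] <- 1L
    pred[total + seq_len(total - overlap)] <- 1L
    list(pred = pred, gt = gt)
  }
  # DSC values 0.9, 1.0, 0.8 -> median 0.9, mean 0.9, SD 0.1
  pairs <- list(mkPair(9L), mkPair(10L), mkPair(8L))
  preds <- lapply(seq_along(pairs), function(i)
    mask3d(pairs[[i]]$pred, subject = paste0("s", i), cohort = "A"))
  gts <- lapply(seq_along(pairs), function(i)
    mask3d(pairs[[i]]$gt, subject = paste0("s", i), cohort = "A"))
  rep <- evaluateSet(preds, gts, hausdorff = FALSE)
  row <- rep@summary[rep@summary$cohort == "A" & rep@summary$metric == "dsc", ]
  expect_equal(row$median, 0.9)
  expect_equal(row$mean, 0.9)
  expect_equal(row$sd, 0.1)
  # single pair: aggregates equal the row, SD reported 0 and flagged
  rep1 <- evaluateSet(preds[1], gts[1], hausdorff = FALSE)
  r1 <- rep1@summary[rep1@summary$metric == "dsc" & rep1@summary$cohort == "overall", ]
  expect_equal(r1$median, rep1@perImage$dsc[1])
  expect_equal(r1$sd, 0)
  expect_false(r1$sdDefined)
  # per-cohort and pooled aggregates recompute from the per-image rows
  set.seed(66)
  preds2 <- c(preds, lapply(1:3, function(i)
    { m <- randomMask(d, 0.3); m@cohortId <- "B"; m@subjectId <- paste0("t", i); m }))
  gts2 <- c(gts, lapply(1:3, function(i)
    { m <- randomMask(d, 0.3); m@cohortId <- "B"; m@subjectId <- paste0("t", i); m }))
  repAll <- evaluateSet(preds2, gts2, hausdorff = TRUE)
  for (cid in c("A", "B", "overall")) {
    sub <- if (cid == "overall") repAll@perImage
           else repAll@perImage[repAll@perImage$cohort == cid, ]
    for (met in c("dsc", "hdMM", "volDiffPct")) {
      row <- repAll@summary[repAll@summary$cohort == cid &
                            repAll@summary$metric == met, ]
      expect_equal(row$median, median(sub[[met]]))
      expect_equal(row$mean, mean(sub[[met]]))
      expect_equal(row$sd, sd(sub[[met]]))
    }
  }
})
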