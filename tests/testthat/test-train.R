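test_that("round-robin sampling visits cohorts in fixed order with fair cycling", {
  # cohorts of sizes 1, 2, 4: in 12 draws the pattern is A,B,C repeated and
  # A's single example appears 4 times
  man <- data.frame(
    subject_id = c("a1", "b1", "b2", "c1", "c2", "c3", "c4"),
    cohort_id = c("A", "B", "B", "C", "C", "C", "C"),
    timepoint = 1L, split = "train",
    image_path = "x", mask_path = "y", stringsAsFactors = FALSE)
  s <- roundRobinSampler(man, seed = 1L)
  draws <- do.call(rbind, lapply(1:12, function(i) s$nextRow()))
  expect_identical(draws$cohort_id, rep(c("A", "B", "C"), 4))
  expect_identical(sum(draws$subject_id == "a1"), 4L)
  # after 4 full cycles every cohort contributed exactly 4 examples
  expect_true(all(table(draws$cohort_id) == 4L))
  # within-cohort queues cycle without starving any example
  expect_true(all(table(draws$subject_id[draws$cohort_id == "B"]) == 2L))

  # same seed reproduces the draw sequence exactly
  s2 <- roundRobinSampler(man, seed = 1L)
  draws2 <- do.call(rbind, lapply(1:12, function(i) s2$nextRow()))
  expect_identical(draws$subject_id, draws2$subject_id)

  # single cohort degenerates to plain cycling
  one <- man[man$cohort_id == "C", ]
  sc <- roundRobinSampler(one, seed = 2L)
  d8 <- vapply(1:8, function(i) sc$nextRow()$subject_id, character(1))
  expect_true(all(table(d8) == 2L))

  # a listed cohort without training rows is an error
  bad <- man
  bad$split[bad$cohort_id == "B"] <- "test"
  expect_error(roundRobinSampler(bad, 1L), "without training rows")
})

test_that("deep-supervision loss matches closed forms and a per-voxel oracle", {
  d <- c(4L, 4L, 4L)
  gt <- array(as.numeric(runif(prod(d)) > 0.5), d)
  half <- array(0.5, d)
  # all outputs constant 0.5: each of the N+1 terms is ln 2
  for (N in c(2, 4)) {
    maps <- replicate(N, half, simplify = FALSE)
    expect_equal(deepSupervisionLoss(maps, half, gt), (N + 1) * log(2),
                 tolerance = 1e-12)
  }
  # near-perfect prediction: loss -> 0 with the clamp
  eps <- 1e-7
  expect_lt(deepSupervisionLoss(list(gt, gt), gt, gt), 3 * 2 * eps * -log(eps) + 1e-6)
  # independent voxel-by-voxel summed-BCE oracle on a random case
  set.seed(31)
  maps <- replicate(3, array(runif(prod(d), 0.01, 0.99), d), simplify = FALSE)
  fused <- array(runif(prod(d), 0.01, 0.99), d)
  oracle <- 0
  for (m in c(maps, list(fused))) {
    tot <- 0
    for (i in seq_len(prod(d)))
      tot <- tot - (gt[i] * log(m[i]) + (1 - gt[i]) * log(1 - m[i]))
    oracle <- oracle + tot / prod(d)
  }
  expect_equal(deepSupervisionLoss(maps, fused, gt), oracle, tolerance = 1e-6)
  expect_error(deepSupervisionLoss(list(half), array(0.5, c(2, 2, 2)), gt),
               "dimensions")
})

test_that("gradient clipping bounds the global norm and passes small gradients", {
  g <- list(a = c(8, 0, 0), b = matrix(0, 2, 2))
  cl <- clipGradients(g, 4)
  expect_equal(cl$a, c(4, 0, 0))
  g2 <- list(a = c(3, 0), b = 0)
  expect_identical(clipGradients(g2, 4), g2)
  g0 <- list(a = c(0, 0), b = matrix(0, 2, 2))
  expect_identical(clipGradients(g0, 4), g0)
  # random trees: post-clip norm never exceeds the bound
  set.seed(9)
  for (i in 1:10) {
    tree <- list(x = array(rnorm(24, sd = 4), c(2, 3, 4)), y = rnorm(5, sd = 4))
    cl <- clipGradients(tree, 4)
    expect_lte(sqrt(sum(unlist(cl)^2)), 4 + 1e-6)
  }
})

test_that("EMA updates follow the closed form and the inertia bound", {
  expect_equal(emaUpdate(list(w = 0), list(w = 1), 0.999)$w, 0.001)
  expect_equal(emaUpdate(list(w = 5), list(w = 3), 0)$w, 3)
  # repeated updates toward a constant converge geometrically
  e <- list(w = 0)
  for (i in 1:50) e <- emaUpdate(e, list(w = 2), 0.9)
  expect_equal(e$w, 2 * (1 - 0.9^50), tolerance = 1e-12)
  # inertia: ||ema_t - ema_{t-1}|| <= (1-decay) ||w_t - ema_{t-1}||
  set.seed(4)
  ema <- list(a = rnorm(10), b = matrix(rnorm(6), 2))
  w <- list(a = rnorm(10), b = matrix(rnorm(6), 2))
  upd <- emaUpdate(ema, w, 0.99)
  lhs <- sqrt(sum((unlist(upd) - unlist(ema))^2))
  rhs <- (1 - 0.99) * sqrt(sum((unlist(w) - unlist(ema))^2))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("training is reproducible, a no-op at 0 steps, and learns the task", {
  man <- microManifest(nSubjects = 3L, seed = 17L)
  net <- buildNetwork(netConfig(nStages = 2, widthMultiplier = 1 / 16, seed = 6L))

  st0 <- trainNetwork(net, man, trainConfig(steps = 0L, seed = 1L))
  expect_identical(st0@network@weights, net@weights)
  expect_identical(st0@emaWeights, net@weights)

  stA <- trainNetwork(net, man, trainConfig(steps = 12L, seed = 2L))
  stB <- trainNetwork(net, man, trainConfig(steps = 12L, seed = 2L))
  expect_identical(stA@lossHistory$loss, stB@lossHistory$loss)
  expect_identical(stA@network@weights, stB@network@weights)

  # short seeded smoke run: loss falls and the trained model beats the
  # untrained one on training-set Dice
  st <- trainNetwork(net, man, trainConfig(steps = 120L, seed = 3L))
  h <- st@lossHistory$loss
  expect_lt(mean(tail(h, 30)), mean(head(h, 30)))
  row <- man[man$split == "train", ][1, ]
  vol <- readVolume(row$image_path)
  gt <- readMask(row$mask_path)
  dscTrained <- dice(binarize(predictProbmap(st, vol), 0.34), gt)
  predUntrained <- binarize(predictProbmap(st0, vol), 0.34)
  dscUntrained <- if (sum(predUntrained@voxels) == 0) 0
                  else dice(predUntrained, gt)
  expect_gt(dscTrained, dscUntrained)
})
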