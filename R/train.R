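# Training: deep-supervision summed cross-entropy, round-robin cohort
# sampling, Nesterov-momentum SGD with global-norm gradient clipping, and
# an exponential moving average of the trainable weights used for
# inference.

#' Construct a training configuration
#'
#' Defaults are the production hyperparameters: learning rate 1e-2,
#' Nesterov momentum 0.9, moving-average decay 0.999, global gradient-norm
#' clip 4, batch size 1 and 30,000 steps. Desk-scale runs override
#' \code{steps}.
#'
#' @param learningRate,momentum,emaDecay,clipNorm,steps,batchSize,seed see
#'   [TrainConfig-class].
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 1e-2, momentum = 0.9, emaDecay = 0.999,
                        clipNorm = 4, steps = 30000L, batchSize = 1L,
                        seed = 1L) {
  new("TrainConfig", learningRate = learningRate, momentum = momentum,
      emaDecay = emaDecay, clipNorm = clipNorm, steps = as.integer(steps),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Round-robin cohort sampler
#'
#' Training pairs are drawn one at a time, visiting cohorts in a fixed
#' (sorted) order each cycle. Within a cohort, examples come from a seeded
#' shuffled queue that reshuffles when exhausted, so over C full cycles
#' every cohort contributes exactly C examples and small cohorts are
#' revisited more often than large ones.
#'
#' @param manifest a manifest data.frame; only \code{split == "train"} rows
#'   are sampled. Every cohort present must have at least one training row.
#' @param seed integer driving the per-cohort shuffles.
#' @return an object with \code{$nextRow()} returning one manifest row
#'   (single-row data.frame) per call, and \code{$cohorts}.
#' @export
roundRobinSampler <- function(manifest, seed = 1L) {
  train <- manifest[manifest$split == "train", , drop = FALSE]
  cohorts <- sort(unique(manifest$cohort_id))
  sizes <- vapply(cohorts, function(cid) sum(train$cohort_id == cid), integer(1))
  if (any(sizes == 0L))
    stop("cohort(s) without training rows: ",
         paste(cohorts[sizes == 0L], collapse = ", "))
  env <- new.env(parent = emptyenv())
  env$queues <- lapply(cohorts, function(cid) integer(0))
  names(env$queues) <- cohorts
  env$cycleCount <- setNames(integer(length(cohorts)), cohorts)
  env$k <- 0L
  rowsOf <- lapply(cohorts, function(cid) which(train$cohort_id == cid))
  names(rowsOf) <- cohorts
  nextRow <- function() {
    cid <- cohorts[(env$k %% length(cohorts)) + 1L]
    env$k <- env$k + 1L
    if (length(env$queues[[cid]]) == 0L) {
      env$cycleCount[cid] <- env$cycleCount[cid] + 1L
      env$queues[[cid]] <- withSeed(
        mixSeed(seed, match(cid, cohorts), env$cycleCount[cid]),
        sample(rowsOf[[cid]]))
    }
    i <- env$queues[[cid]][1L]
    env$queues[[cid]] <- env$queues[[cid]][-1L]
    train[i, , drop = FALSE]
  }
  list(nextRow = nextRow, cohorts = cohorts)
}

clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# Mean binary cross-entropy of probabilities p against binary y.
bceMean <- function(p, y, eps = 1e-7) {
  p <- clampProb(p, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Deep-supervision loss
#'
#' Summed cross-entropy of each stage map and the fused prediction against
#' the ground-truth mask: each of the N+1 terms is the per-voxel binary
#' cross-entropy averaged over voxels (so the loss magnitude is independent
#' of lattice size), and the terms are summed.
#'
#' @param stageMaps list of N probability lattices at input resolution.
#' @param fused the fused probability lattice.
#' @param gt ground-truth [ICCMask-class] or binary array of equal dims.
#' @param eps probability clamp keeping the loss finite.
#' @return non-negative scalar.
#' @export
deepSupervisionLoss <- function(stageMaps, fused, gt, eps = 1e-7) {
  y <- if (is(gt, "ICCMask")) gt@voxels else gt
  if (is(fused, "ProbMap")) fused <- fused@voxels
  for (m in c(stageMaps, list(fused)))
    if (!identical(dim(if (is(m, "ProbMap")) m@voxels else m), dim(y)))
      stop("stage/fused map dimensions must match ground truth")
  terms <- vapply(stageMaps, function(m)
    bceMean(if (is(m, "ProbMap")) m@voxels else m, y, eps), numeric(1))
  sum(terms) + bceMean(fused, y, eps)
}

#' Clip gradients to a global L2 norm
#'
#' If the concatenated L2 norm of all gradients exceeds \code{clipNorm},
#' every gradient is scaled by \code{clipNorm / norm}; otherwise gradients
#' pass unchanged. All-zero gradients are returned as is.
#'
#' @param grads nested list of gradient arrays.
#' @param clipNorm positive bound (production value 4).
#' @return the (possibly scaled) gradient tree.
#' @export
clipGradients <- function(grads, clipNorm = 4) {
  g <- sqrt(wSumSq(grads))
  if (!is.finite(g)) stop("non-finite gradient norm")
  if (g > clipNorm && g > 0) grads <- wMap(function(a) a * (clipNorm / g), grads)
  grads
}

#' One exponential-moving-average update
#'
#' \code{ema <- decay * ema + (1 - decay) * weights}, elementwise over the
#' weight tree.
#'
#' @param emaWeights,weights weight trees of identical shape.
#' @param decay in [0, 1).
#' @return updated EMA tree.
#' @export
emaUpdate <- function(emaWeights, weights, decay) {
  wMap2(function(e, w) decay * e + (1 - decay) * w, emaWeights, weights)
}

# Loss and full gradient tree for one training pair.  x3d: preprocessed
# intensity lattice; y3d: aligned binary target.
lossAndGrads <- function(net, x3d, y3d, eps = 1e-7) {
  N <- net@config@nStages
  fwd <- forwardPass(net, x3d, keepCache = TRUE)
  cache <- fwd$cache
  V <- length(y3d)
  loss <- deepSupervisionLoss(fwd$stageMaps, fwd$fused, y3d, eps)

  grads <- list(stages = vector("list", N), fuse = NULL)
  # exact gradient of mean BCE w.r.t. the pre-sigmoid score
  dFused <- (fwd$fused - y3d) / V
  fuseW <- net@weights$fuse$W
  dFuseW <- matrix(0, N, 1)
  for (s in seq_len(N))
    dFuseW[s, 1] <- sum(fwd$stageScores[[s]] * dFused)
  grads$fuse <- list(W = dFuseW, b = sum(dFused))

  # gradient reaching each upsampled pre-sigmoid score map
  dUp <- vector("list", N)
  for (s in seq_len(N))
    dUp[[s]] <- (fwd$stageMaps[[s]] - y3d) / V + fuseW[s, 1] * dFused

  dFeat <- vector("list", N)  # gradient w.r.t. each stage's final feature map
  for (s in seq_len(N)) {
    f <- 2L^(s - 1L)
    dScore3 <- if (f == 1L) dUp[[s]]
               else cpp_upsample_backward(dUp[[s]], f, dim(cache$stages[[s]]$feat)[1:3])
    feat <- cache$stages[[s]]$feat
    dFt <- dim(feat)
    Hmat <- matrix(feat, prod(dFt[1:3]), dFt[4])
    dS <- matrix(dScore3, ncol = 1)
    sw <- net@weights$stages[[s]]$score
    grads$stages[[s]] <- list(conv = vector("list", length(cache$stages[[s]]$z)),
                              score = list(W = crossprod(Hmat, dS), b = sum(dS)))
    dFeat[[s]] <- array(dS %*% t(sw$W), dFt)
  }

  g <- dFeat[[N]]
  for (s in rev(seq_len(N))) {
    st <- net@weights$stages[[s]]
    cs <- cache$stages[[s]]
    for (l in rev(seq_along(st$conv))) {
      dz <- g * (cs$z[[l]] > 0)
      bk <- cpp_conv3d_backward(cs$convIn[[l]], st$conv[[l]]$W, dz)
      grads$stages[[s]]$conv[[l]] <- list(W = bk$dw, b = bk$db)
      g <- bk$dx
    }
    if (s > 1L) {
      csPrev <- cache$stages[[s - 1L]]
      g <- cpp_maxpool_backward(g, csPrev$poolIdx, csPrev$prePoolDim)
      g <- g + dFeat[[s - 1L]]
    }
  }
  list(loss = loss, grads = grads, fused = fwd$fused)
}

#' Train a network
#'
#' Runs exactly \code{cfg@steps} optimization steps of: draw one training
#' pair round-robin by cohort, forward pass, deep-supervision loss,
#' backpropagation, global-norm gradient clipping, Nesterov-momentum SGD
#' update, and an EMA update of the trainable weights. Volumes are
#' preprocessed once and cached; ground-truth masks are carried into
#' network space with each volume's PrepRecord. The EMA uses the
#' TensorFlow-style warm-up, effective decay \code{min(emaDecay,
#' (1 + t) / (10 + t))} at step t, so short desk-scale runs are not
#' dominated by the random initialisation.
#'
#' The run is fully reproducible from (network seed, cfg seed, manifest).
#'
#' @param net a [Network-class] (its weights are the starting point).
#' @param manifest manifest data.frame with a non-empty training split.
#' @param cfg a [TrainConfig-class].
#' @param verbose print progress every 200 steps.
#' @return a [TrainState-class] carrying current and EMA weights and the
#'   per-step loss history.
#' @export
trainNetwork <- function(net, manifest, cfg, verbose = FALSE) {
  validObject(cfg)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(train) == 0L) stop("manifest training split is empty")
  N <- net@config@nStages

  paths <- unique(train$image_path)
  cacheData <- new.env(parent = emptyenv())
  loadPair <- function(imgPath, maskPath) {
    key <- imgPath
    if (is.null(cacheData[[key]])) {
      vol <- readVolume(imgPath)
      pp <- preprocess(vol, N)
      gt <- prepMaskArray(readMask(maskPath)@voxels, pp$record)
      cacheData[[key]] <- list(x = pp$volume@voxels, y = gt)
    }
    cacheData[[key]]
  }

  sampler <- roundRobinSampler(manifest, cfg@seed)
  weights <- net@weights
  velocity <- wMap(function(a) a * 0, weights)
  ema <- weights
  lr <- cfg@learningRate
  mu <- cfg@momentum
  hist <- data.frame(step = integer(cfg@steps), cohort = character(cfg@steps),
                     loss = numeric(cfg@steps), stringsAsFactors = FALSE)

  for (t in seq_len(cfg@steps)) {
    row <- sampler$nextRow()
    pair <- loadPair(row$image_path, row$mask_path)
    net@weights <- weights
    lg <- lossAndGrads(net, pair$x, pair$y)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite loss at step %d (cohort %s, subject %s)",
                   t, row$cohort_id, row$subject_id))
    grads <- clipGradients(lg$grads, cfg@clipNorm)
    velocity <- wMap2(function(v, g) mu * v + g, velocity, grads)
    weights <- wMap2(function(w, vg) w - lr * vg, weights,
                     wMap2(function(g, v) g + mu * v, grads, velocity))
    d <- min(cfg@emaDecay, (1 + t) / (10 + t))
    ema <- emaUpdate(ema, weights, d)
    hist$step[t] <- t
    hist$cohort[t] <- row$cohort_id
    hist$loss[t] <- lg$loss
    if (verbose && t %% 200L == 0L)
      message(sprintf("step %d/%d loss %.4f", t, cfg@steps, lg$loss))
  }
  net@weights <- weights
  new("TrainState", network = net, emaWeights = ema, step = cfg@steps,
      lossHistory = hist, config = cfg)
}
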