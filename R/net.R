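# Deeply supervised multi-resolution volumetric network.
#
# Encoder: N stages of (3x3x3 conv + ReLU) blocks, connected by N-1
# 2x2x2/stride-2 max-pooling layers.  Decoder: per stage a 1x1x1 score
# convolution to a single channel, a fixed (non-learning) trilinear
# upsampling back to input resolution, and one final 1x1x1 convolution
# fusing the N upsampled score maps, bounded to [0,1] by a sigmoid.  The
# fuse layer consumes the pre-sigmoid score maps; each stage map passes
# through its own sigmoid for the deep-supervision losses.

#' Construct an architecture configuration
#'
#' Defaults follow the production 5-stage schedule: conv-layer counts
#' (2,2,3,3,3) and filter counts (32,128,256,512,1024), both truncated to
#' \code{nStages}; the 2-4 stage variants are prefixes of that schedule.
#' \code{widthMultiplier} scales every filter count (rounded, floor 1) for
#' desk-scale runs, e.g. 1/16.
#'
#' @param nStages stage count N in 2..5.
#' @param convCounts,filterCounts per-stage schedules of length
#'   \code{nStages} (before width scaling).
#' @param widthMultiplier positive filter-count scaling, default 1.
#' @param seed weight-initialisation seed.
#' @return a validated [NetConfig-class].
#' @export
netConfig <- function(nStages = 5L,
                      convCounts = c(2L, 2L, 3L, 3L, 3L)[seq_len(nStages)],
                      filterCounts = c(32L, 128L, 256L, 512L, 1024L)[seq_len(nStages)],
                      widthMultiplier = 1, seed = 1L) {
  scaled <- pmax(1L, as.integer(round(filterCounts * widthMultiplier)))
  new("NetConfig", nStages = as.integer(nStages),
      convCounts = as.integer(convCounts), filterCounts = scaled,
      widthMultiplier = widthMultiplier, seed = as.integer(seed))
}

#' Build the deeply supervised segmentation network
#'
#' Constructs the layer graph and initialises all trainable weights
#' (variance-scaling for convolutions; the fuse convolution starts as an
#' equal-weight average of the stages with zero bias). Trilinear
#' upsampling layers are fixed interpolation operators and carry no
#' weights. Identical configuration and seed give bit-identical initial
#' weights.
#'
#' @param cfg a [NetConfig-class].
#' @return a [Network-class].
#' @examples
#' net <- buildNetwork(netConfig(nStages = 5))
#' summarizeArchitecture(net)$encoderConvCount  # 13
#' @export
buildNetwork <- function(cfg) {
  validObject(cfg)
  N <- cfg@nStages
  layers <- list()
  weights <- list(stages = vector("list", N), fuse = NULL)
  withSeed(cfg@seed, {
    cin <- 1L
    for (s in seq_len(N)) {
      cout <- cfg@filterCounts[s]
      convs <- vector("list", cfg@convCounts[s])
      for (l in seq_len(cfg@convCounts[s])) {
        fanIn <- 27 * cin
        W <- array(rnorm(27 * cin * cout, sd = sqrt(2 / fanIn)),
                   c(3L, 3L, 3L, cin, cout))
        convs[[l]] <- list(W = W, b = numeric(cout))
        layers[[length(layers) + 1L]] <- list(
          type = "conv3x3x3_relu", stage = s, inChannels = cin, outChannels = cout)
        cin <- cout
      }
      score <- list(W = matrix(rnorm(cout, sd = sqrt(1 / cout)), cout, 1), b = 0)
      layers[[length(layers) + 1L]] <- list(
        type = "score1x1x1", stage = s, inChannels = cout, outChannels = 1L)
      layers[[length(layers) + 1L]] <- list(
        type = "upsample_trilinear", stage = s, factor = 2L^(s - 1L),
        nonLearning = TRUE)
      weights$stages[[s]] <- list(conv = convs, score = score)
      if (s < N)
        layers[[length(layers) + 1L]] <- list(type = "maxpool2x2x2", afterStage = s)
    }
    weights$fuse <- list(W = matrix(1 / N, N, 1), b = 0)
    layers[[length(layers) + 1L]] <- list(type = "fuse1x1x1", inChannels = N,
                                          outChannels = 1L)
    layers[[length(layers) + 1L]] <- list(type = "sigmoid")
  })
  new("Network", config = cfg, layers = layers, weights = weights)
}

# 1x1x1 convolution as a channel-mixing matrix product.
conv1x1 <- function(h4d, W, b) {
  d <- dim(h4d)
  H <- matrix(h4d, prod(d[1:3]), d[4])
  Y <- H %*% W
  if (length(b) == 1L) Y <- Y + b else Y <- sweep(Y, 2, b, "+")
  array(Y, c(d[1:3], ncol(W)))
}

#' Forward pass through the network
#'
#' @param net a [Network-class]; \code{weights} optionally overrides the
#'   network's weight tree (used for EMA inference).
#' @param x a 3D numeric array or network-space [HeadVolume-class] whose
#'   dimensions are divisible by 2^(N-1).
#' @param keepCache keep intermediate activations for backpropagation.
#' @param weights optional replacement weight tree.
#' @return list with \code{stageScores} (pre-sigmoid, input resolution),
#'   \code{stageMaps} (sigmoid of the scores), \code{fusedScore},
#'   \code{fused} (values in [0,1]) and, if requested, \code{cache}.
#' @export
forwardPass <- function(net, x, keepCache = FALSE, weights = NULL) {
  if (is(x, "HeadVolume")) x <- x@voxels
  if (is.null(weights)) weights <- net@weights
  N <- net@config@nStages
  d <- dim(x)
  m <- 2L^(N - 1L)
  if (any(d %% m != 0L))
    stop(sprintf("input dims (%s) must be divisible by %d for %d stages",
                 paste(d, collapse = "x"), m, N))
  h <- array(x, c(d, 1L))
  cache <- list(stages = vector("list", N))
  stageScores <- vector("list", N)
  for (s in seq_len(N)) {
    st <- weights$stages[[s]]
    convIn <- vector("list", length(st$conv))
    zs <- vector("list", length(st$conv))
    for (l in seq_along(st$conv)) {
      convIn[[l]] <- h
      z <- cpp_conv3d_forward(h, st$conv[[l]]$W, st$conv[[l]]$b)
      zs[[l]] <- z
      h <- z * (z > 0)
    }
    sc <- conv1x1(h, st$score$W, st$score$b)
    sc3 <- array(sc, dim(sc)[1:3])
    f <- 2L^(s - 1L)
    stageScores[[s]] <- if (f == 1L) sc3 else cpp_upsample_forward(sc3, f)
    if (keepCache)
      cache$stages[[s]] <- list(convIn = convIn, z = zs, feat = h)
    if (s < N) {
      mp <- cpp_maxpool_forward(h)
      if (keepCache) {
        cache$stages[[s]]$poolIdx <- mp$idx
        cache$stages[[s]]$prePoolDim <- dim(h)
      }
      h <- mp$y
    }
  }
  fw <- weights$fuse$W
  fusedScore <- array(0, d)
  for (s in seq_len(N)) fusedScore <- fusedScore + fw[s, 1] * stageScores[[s]]
  fusedScore <- fusedScore + weights$fuse$b
  out <- list(stageScores = stageScores,
              stageMaps = lapply(stageScores, sigmoid),
              fusedScore = fusedScore, fused = sigmoid(fusedScore))
  if (keepCache) out$cache <- cache
  out
}

#' Summarize a constructed network
#'
#' Counts are computed by traversing the built layer graph and weight tree,
#' not read back from the configuration.
#'
#' @param net a [Network-class].
#' @return list with encoderConvCount, poolCount, decoderConvCount
#'   (per-stage score convs + fuse conv), parameterCount (trainable) and
#'   stageResolutions (fraction of input resolution per stage).
#' @export
summarizeArchitecture <- function(net) {
  types <- vapply(net@layers, function(l) l$type, character(1))
  N <- net@config@nStages
  list(encoderConvCount = sum(types == "conv3x3x3_relu"),
       poolCount = sum(types == "maxpool2x2x2"),
       decoderConvCount = sum(types %in% c("score1x1x1", "fuse1x1x1")),
       upsampleCount = sum(types == "upsample_trilinear"),
       parameterCount = wCount(net@weights),
       stageResolutions = 1 / 2^(seq_len(N) - 1))
}

#' Save or load a checkpoint
#'
#' A checkpoint directory holds the serialized weight trees (current and
#' EMA) plus a JSON architecture descriptor so checkpoints are
#' self-describing.
#'
#' @param state a [TrainState-class].
#' @param dir checkpoint directory.
#' @return \code{loadCheckpoint}: a [TrainState-class].
#' @export
saveCheckpoint <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- state@network@config
  desc <- list(nStages = cfg@nStages, convCounts = cfg@convCounts,
               filterCounts = cfg@filterCounts,
               widthMultiplier = cfg@widthMultiplier, seed = cfg@seed,
               step = state@step,
               trainConfig = list(learningRate = state@config@learningRate,
                                  momentum = state@config@momentum,
                                  emaDecay = state@config@emaDecay,
                                  clipNorm = state@config@clipNorm,
                                  steps = state@config@steps,
                                  seed = state@config@seed))
  jsonlite::write_json(desc, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(weights = state@network@weights, emaWeights = state@emaWeights,
               lossHistory = state@lossHistory), file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  desc <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  blob <- readRDS(file.path(dir, "weights.rds"))
  cfg <- new("NetConfig", nStages = as.integer(desc$nStages),
             convCounts = as.integer(desc$convCounts),
             filterCounts = as.integer(desc$filterCounts),
             widthMultiplier = desc$widthMultiplier,
             seed = as.integer(desc$seed))
  net <- buildNetwork(cfg)
  net@weights <- blob$weights
  tc <- desc$trainConfig
  new("TrainState", network = net, emaWeights = blob$emaWeights,
      step = as.integer(desc$step), lossHistory = blob$lossHistory,
      config = trainConfig(learningRate = tc$learningRate,
                           momentum = tc$momentum, emaDecay = tc$emaDecay,
                           clipNorm = tc$clipNorm, steps = tc$steps,
                           seed = tc$seed))
}
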