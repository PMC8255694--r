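# Desk-scale replications of the two experimental designs — cohort
# diversity vs training-set size, and stage-count sweep — plus the
# longitudinal consistency test, on synthetic cohorts.

#' Default desk-scale synthetic cohorts
#'
#' Four cohorts emulating inter-study heterogeneity: they differ in global
#' contrast scaling, tissue-mean profile, noise level, bias-field strength
#' and head-size range, while sharing lattice and spacing. Defaults are
#' 32^3 lattices at 2 mm, sized so one cohort-diversity experiment runs on
#' a single CPU.
#'
#' @param nSubjects subjects per cohort.
#' @param nTimepoints scans per subject.
#' @param dims,voxelSpacing lattice geometry shared by all cohorts.
#' @param seed master seed; each cohort derives its own stream from it.
#' @return list of 4 [CohortSpec-class].
#' @export
deskCohortSpecs <- function(nSubjects = 40L, nTimepoints = 1L,
                            dims = c(32L, 32L, 32L), voxelSpacing = c(2, 2, 2),
                            seed = 1L) {
  base <- c(background = 0, scalp = 90, skull = 35, csf = 15, brain = 70)
  list(
    cohortSpec("A", nSubjects, nTimepoints, tissueMeans = base,
               noiseSigma = 4, biasAmplitude = 0.10,
               radiiMin = c(15, 16, 14), radiiMax = c(19, 20, 18),
               voxelSpacing = voxelSpacing, dims = dims,
               seed = mixSeed(seed, 1)),
    cohortSpec("B", nSubjects, nTimepoints, tissueMeans = base * 0.75,
               noiseSigma = 6, biasAmplitude = 0.20,
               radiiMin = c(14, 15, 13), radiiMax = c(18, 19, 17),
               voxelSpacing = voxelSpacing, dims = dims,
               seed = mixSeed(seed, 2)),
    cohortSpec("C", nSubjects, nTimepoints, tissueMeans = base * 1.25,
               noiseSigma = 8, biasAmplitude = 0.15,
               radiiMin = c(16, 17, 15), radiiMax = c(20, 21, 19),
               voxelSpacing = voxelSpacing, dims = dims,
               seed = mixSeed(seed, 3)),
    cohortSpec("D", nSubjects, nTimepoints,
               tissueMeans = c(background = 0, scalp = 100, skull = 45,
                               csf = 20, brain = 60),
               noiseSigma = 5, biasAmplitude = 0.30,
               radiiMin = c(15, 16, 14), radiiMax = c(19, 20, 18),
               voxelSpacing = voxelSpacing, dims = dims,
               seed = mixSeed(seed, 4)))
}

#' Construct an experiment plan
#'
#' @param levels cohort-count levels to test.
#' @param trainingsPerLevel trainings at each level below the full cohort
#'   set (the full set always gets exactly one training).
#' @param coverage require every cohort to appear in at least one subset
#'   per level (greedy repair after the seeded random draw).
#' @param trainConfig shared [TrainConfig-class] for all trainings.
#' @param netSeed base seed for network initialisation.
#' @param masterSeed drives subset selection and per-training seeds.
#' @return an [ExperimentPlan-class].
#' @export
experimentPlan <- function(levels, trainingsPerLevel = 3L, coverage = TRUE,
                           trainConfig = iccseg::trainConfig(steps = 500L),
                           netSeed = 1L, masterSeed = 1L) {
  if (any(trainingsPerLevel < 1L)) stop("trainingsPerLevel must be >= 1")
  new("ExperimentPlan", levels = as.integer(levels),
      trainingsPerLevel = as.integer(trainingsPerLevel),
      coverage = coverage, trainConfig = trainConfig,
      netSeed = as.integer(netSeed), masterSeed = as.integer(masterSeed))
}

subsetKey <- function(s) paste(sort(s), collapse = "+")

#' Select cohort subsets for a diversity level
#'
#' Draws \code{nTrainings} distinct size-\code{level} subsets of the
#' cohorts (seeded). Under the coverage constraint, a greedy repair swaps
#' over-represented cohorts out until every cohort appears in at least one
#' subset; infeasibility is an error, never silently relaxed. For
#' \code{level == length(cohorts)} there is exactly one subset.
#'
#' @param cohorts character vector of cohort ids.
#' @param level subset size (<= number of cohorts).
#' @param nTrainings number of subsets.
#' @param seed integer. @param coverage enforce the coverage constraint.
#' @return list of character vectors (sorted within each subset).
#' @export
selectCohortSubsets <- function(cohorts, level, nTrainings, seed = 1L,
                                coverage = TRUE) {
  n <- length(cohorts)
  if (level > n) stop("level exceeds the number of cohorts")
  if (level == n) return(list(sort(cohorts)))
  if (choose(n, level) < nTrainings)
    stop("fewer distinct subsets exist than trainings requested")
  if (coverage && nTrainings * level < n)
    stop("coverage constraint infeasible: nTrainings * level < number of cohorts")
  subsets <- withSeed(mixSeed(seed, level, 17L), {
    out <- list()
    keys <- character(0)
    while (length(out) < nTrainings) {
      cand <- sort(sample(cohorts, level))
      k <- subsetKey(cand)
      if (!(k %in% keys)) { out[[length(out) + 1L]] <- cand; keys <- c(keys, k) }
    }
    out
  })
  if (coverage) {
    repeat {
      counts <- table(factor(unlist(subsets), levels = cohorts))
      missing <- names(counts)[counts == 0]
      if (length(missing) == 0) break
      c0 <- missing[1]
      # swap out the globally most redundant member of some subset
      done <- FALSE
      for (ord in order(-counts)) {
        rich <- cohorts[ord]
        if (counts[rich] < 2) break
        for (i in seq_along(subsets)) {
          if (rich %in% subsets[[i]] && !(c0 %in% subsets[[i]])) {
            cand <- sort(c(setdiff(subsets[[i]], rich), c0))
            if (!(subsetKey(cand) %in% vapply(subsets, subsetKey, character(1)))) {
              subsets[[i]] <- cand
              done <- TRUE
              break
            }
          }
        }
        if (done) break
      }
      if (!done) stop("coverage constraint could not be satisfied by repair")
    }
  }
  subsets
}

trainAndScore <- function(manifest, trainCohorts, netCfg, tCfg, threshold = 0.34) {
  trainMan <- manifest[manifest$split == "train" &
                         manifest$cohort_id %in% trainCohorts, , drop = FALSE]
  net <- buildNetwork(netCfg)
  state <- trainNetwork(net, trainMan, tCfg)
  test <- manifest[manifest$split == "test", , drop = FALSE]
  rows <- lapply(seq_len(nrow(test)), function(i) {
    vol <- readVolume(test$image_path[i], subjectId = test$subject_id[i],
                      cohortId = test$cohort_id[i],
                      timepoint = test$timepoint[i])
    gt <- readMask(test$mask_path[i], subjectId = test$subject_id[i],
                   cohortId = test$cohort_id[i], timepoint = test$timepoint[i])
    pred <- binarize(predictProbmap(state, vol), threshold)
    d <- if (sum(pred@voxels) == 0) 0 else dice(pred, gt)
    data.frame(subject = test$subject_id[i], cohort = test$cohort_id[i],
               dsc = d, volDiffPct = volumeDiffPct(pred, gt),
               stringsAsFactors = FALSE)
  })
  list(state = state, perImage = do.call(rbind, rows),
       trainSize = nrow(trainMan))
}

#' Run the cohort-diversity experiment
#'
#' For each cohort-count level, trains one model per selected subset on
#' that subset's training rows (the test split is always the full,
#' all-cohort test set), and collects per-test-image DSC and percent
#' volume differences. Fully seeded: rerunning with the same plan,
#' manifest and master seed reproduces the tables.
#'
#' @param plan an [ExperimentPlan-class].
#' @param manifest dataset manifest (from [synthDataset()]).
#' @param netConfigTemplate a [NetConfig-class]; each training reuses it
#'   with a derived seed.
#' @param threshold binarization threshold (default 0.34).
#' @return list with \code{perImage} (one row per training x test image),
#'   \code{byTraining} (per-training median/SD of DSC) and \code{byLevel}
#'   (median/mean/SD of DSC pooled per level, and the mean of the
#'   per-training SDs as \code{meanTrainingSd}).
#' @export
runDiversityExperiment <- function(plan, manifest, netConfigTemplate,
                                   threshold = 0.34) {
  cohorts <- sort(unique(manifest$cohort_id))
  all <- list()
  for (L in plan@levels) {
    subsets <- if (L == length(cohorts)) list(sort(cohorts))
      else selectCohortSubsets(cohorts, L, plan@trainingsPerLevel,
                               seed = plan@masterSeed, coverage = plan@coverage)
    for (j in seq_along(subsets)) {
      netCfg <- netConfig(nStages = netConfigTemplate@nStages,
                          convCounts = netConfigTemplate@convCounts,
                          filterCounts = netConfigTemplate@filterCounts,
                          widthMultiplier = 1,
                          seed = mixSeed(plan@netSeed, L, j))
      tCfg <- plan@trainConfig
      tCfg@seed <- mixSeed(plan@masterSeed, L, j, 23L)
      res <- trainAndScore(manifest, subsets[[j]], netCfg, tCfg, threshold)
      df <- res$perImage
      df$level <- L
      df$training <- j
      df$subset <- subsetKey(subsets[[j]])
      df$trainSize <- res$trainSize
      all[[length(all) + 1L]] <- df
    }
  }
  per <- do.call(rbind, all)
  byTraining <- do.call(rbind, lapply(split(per, list(per$level, per$training), drop = TRUE),
    function(d) data.frame(level = d$level[1], training = d$training[1],
                           subset = d$subset[1], trainSize = d$trainSize[1],
                           medianDsc = median(d$dsc), sdDsc = sd(d$dsc),
                           stringsAsFactors = FALSE)))
  byLevel <- do.call(rbind, lapply(split(per, per$level), function(d) {
    bt <- byTraining[byTraining$level == d$level[1], , drop = FALSE]
    data.frame(level = d$level[1], nTrainings = nrow(bt),
               medianDsc = median(d$dsc), meanDsc = mean(d$dsc),
               sdDsc = sd(d$dsc), meanTrainingSd = mean(bt$sdDsc),
               stringsAsFactors = FALSE)
  }))
  rownames(byTraining) <- rownames(byLevel) <- NULL
  list(perImage = per, byTraining = byTraining, byLevel = byLevel)
}

#' Run the stage-count sweep
#'
#' Trains one model per requested stage count on the full training split
#' and evaluates each on the test split.
#'
#' @param stages subset of 2:5.
#' @param manifest dataset manifest.
#' @param widthMultiplier filter scaling shared by all models.
#' @param tCfg shared [TrainConfig-class].
#' @param masterSeed drives per-stage net/training seeds.
#' @param threshold binarization threshold.
#' @param hausdorff include the Hausdorff distance in the reports.
#' @return list with \code{reports} (named list of [EvalReport-class] keyed
#'   by stage count) and \code{dscTable} (long data.frame stage/subject/dsc).
#' @export
runStageExperiment <- function(stages, manifest, widthMultiplier = 1 / 16,
                               tCfg = trainConfig(steps = 500L),
                               masterSeed = 1L, threshold = 0.34,
                               hausdorff = FALSE) {
  if (!all(stages %in% 2:5)) stop("stage counts must lie in 2..5")
  test <- manifest[manifest$split == "test", , drop = FALSE]
  reports <- list()
  dscTab <- list()
  for (s in stages) {
    net <- buildNetwork(netConfig(nStages = s, widthMultiplier = widthMultiplier,
                                  seed = mixSeed(masterSeed, s)))
    tc <- tCfg
    tc@seed <- mixSeed(masterSeed, s, 31L)
    state <- trainNetwork(net, manifest, tc)
    preds <- list(); gts <- list()
    for (i in seq_len(nrow(test))) {
      vol <- readVolume(test$image_path[i], subjectId = test$subject_id[i],
                        cohortId = test$cohort_id[i], timepoint = test$timepoint[i])
      gts[[i]] <- readMask(test$mask_path[i], subjectId = test$subject_id[i],
                           cohortId = test$cohort_id[i], timepoint = test$timepoint[i])
      preds[[i]] <- binarize(predictProbmap(state, vol), threshold)
    }
    rep <- evaluateSet(preds, gts, hausdorff = hausdorff,
                       onEmptyPred = "score")
    reports[[as.character(s)]] <- rep
    dscTab[[as.character(s)]] <- data.frame(stage = s,
                                            subject = rep@perImage$subject,
                                            dsc = rep@perImage$dsc,
                                            stringsAsFactors = FALSE)
  }
  list(reports = reports, dscTable = do.call(rbind, dscTab))
}

#' Desk-scale training benchmark
#'
#' The package's reference desk-scale run: generate the four default desk
#' cohorts (30 training + 10 test subjects each, 32^3 lattices at 2 mm),
#' train a 3-stage width-1/16 network with the production hyperparameters
#' for \code{steps} optimization steps, and evaluate Dice on the 40
#' held-out phantoms at the default threshold. Everything derives from the
#' single \code{seed}.
#'
#' @param seed master seed.
#' @param steps training steps (default 2000).
#' @param outDir where the synthetic dataset is written.
#' @param nStages,widthMultiplier network scale.
#' @param threshold binarization threshold.
#' @return list(state, manifest, report = [EvalReport-class], medianDsc).
#' @export
runDeskBenchmark <- function(seed = 1L, steps = 2000L,
                             outDir = tempfile("deskbench"),
                             nStages = 3L, widthMultiplier = 1 / 16,
                             threshold = 0.34) {
  specs <- deskCohortSpecs(nSubjects = 40L, seed = mixSeed(seed, 1))
  manifest <- synthDataset(specs, c(train = 0.75, eval = 0, test = 0.25),
                           seed = mixSeed(seed, 5), outDir = outDir)
  net <- buildNetwork(netConfig(nStages = nStages,
                                widthMultiplier = widthMultiplier,
                                seed = mixSeed(seed, 2)))
  state <- trainNetwork(net, manifest,
                        trainConfig(steps = steps, seed = mixSeed(seed, 3)))
  test <- manifest[manifest$split == "test", , drop = FALSE]
  preds <- list(); gts <- list()
  for (i in seq_len(nrow(test))) {
    vol <- readVolume(test$image_path[i], subjectId = test$subject_id[i],
                      cohortId = test$cohort_id[i], timepoint = test$timepoint[i])
    gts[[i]] <- readMask(test$mask_path[i], subjectId = test$subject_id[i],
                         cohortId = test$cohort_id[i], timepoint = test$timepoint[i])
    preds[[i]] <- binarize(predictProbmap(state, vol), threshold)
  }
  report <- evaluateSet(preds, gts, hausdorff = TRUE)
  list(state = state, manifest = manifest, report = report,
       medianDsc = median(report@perImage$dsc))
}

#' Longitudinal consistency of a trained model
#'
#' Predicts ICC masks for every timepoint of each subject in the manifest
#' and reports the per-subject maximum volume difference in cm^3 and its
#' median across subjects. Subjects with a single timepoint are excluded
#' with a warning.
#'
#' @param state a [TrainState-class].
#' @param manifest manifest rows of the longitudinal subjects.
#' @param threshold binarization threshold.
#' @return a [LongitudinalReport-class].
#' @export
runLongitudinalTest <- function(state, manifest, threshold = 0.34) {
  bySubj <- split(manifest, manifest$subject_id)
  nTp <- vapply(bySubj, nrow, integer(1))
  if (any(nTp < 2L)) {
    warning("excluding subject(s) with a single timepoint: ",
            paste(names(bySubj)[nTp < 2L], collapse = ", "))
    bySubj <- bySubj[nTp >= 2L]
  }
  if (length(bySubj) == 0) stop("no subjects with >= 2 timepoints")
  masks <- lapply(bySubj, function(rows) {
    lapply(seq_len(nrow(rows)), function(i) {
      vol <- readVolume(rows$image_path[i])
      binarize(predictProbmap(state, vol), threshold)
    })
  })
  longitudinalMaxDiff(masks)
}
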