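# iccseg — deeply supervised volumetric segmentation of the intracranial cavity

`iccseg` is an R package for segmenting the **intracranial cavity (ICC)** —
brain tissue plus the surrounding CSF out to the dura mater — from whole-head
T1-weighted structural MRI. The ICC is age-stable, which makes it the
reference volume of choice for normalising brain measures in longitudinal and
multi-cohort studies; producing it quickly and consistently is a classic
pipeline bottleneck that this package addresses with a compact deep-learning
stack written for desk-scale scientific use.

The package implements, end to end:

* **Network.** An N-stage (N ∈ 2..5) volumetric CNN: 3×3×3 conv/ReLU encoder
  blocks (layer schedule 2,2,3,3,3; filters 32,128,256,512,1024) joined by
  N−1 max-pooling layers; per-stage 1×1×1 score convolutions; fixed
  (non-learning) trilinear upsampling back to input resolution; a 1×1×1 fuse
  convolution and sigmoid. For N = 5: 13 encoder convolutions, 4 pools,
  6 decoder convolutions. Forward *and* backward passes are implemented in
  the package (Rcpp/RcppArmadillo); no external deep-learning framework is
  used.
* **Training.** Deep supervision — summed per-voxel binary cross-entropy of
  each stage map and the fused map,
  `L = Σ_{s=1..N} BCE(σ(u_s), y) + BCE(σ(Σ w_s u_s + b), y)` —
  optimised by Nesterov-momentum SGD (lr 1e-2, momentum 0.9, batch 1) with
  global gradient-norm clipping at 4 and an exponential moving average
  (decay 0.999) of the weights for inference, sampling training pairs
  round-robin by cohort so small cohorts stay influential.
* **Preprocessing.** Non-destructive auto-crop → zero-mean/unit-SD
  normalisation → zero-padding to dimensions divisible by 2^(N−1), recorded
  in a `PrepRecord` and exactly invertible back to native space.
* **Inference.** Probability maps in [0,1], binarised at the empirically
  calibrated strict threshold p > 0.34, plus the calibration sweep itself
  (maximise median Dice, tie-break on interquartile range).
* **Metrics.** Dice `DSC = 2|A∩B|/(|A|+|B|)`, exact symmetric Hausdorff
  distance in mm via distance transforms
  (`HD = max(h(A,B), h(B,A))`, `h(A,B) = max_{a∈A} min_{b∈B} ‖a−b‖`),
  false-negative/false-positive percentages, signed percent volume
  difference, longitudinal per-subject max volume difference, and
  cohort-stratified median/mean/SD reports.
* **Synthetic cohorts.** A seeded head-phantom generator (nested ellipsoidal
  shells with analytic ICC volume, T1-like contrast, bias field, noise,
  rigid pose; NIfTI-1 output with TSV manifests) emulating multi-cohort
  heterogeneity, plus harnesses for cohort-diversity, stage-count and
  longitudinal-consistency experiments.

## Worked example

Train the desk-scale reference configuration (four synthetic cohorts of
40 subjects at 32³/2 mm; 3-stage width-1/16 network; 2,000 steps) and
evaluate on the 40 held-out phantoms:

```r
library(iccseg)
bench <- runDeskBenchmark(seed = 1, steps = 2000)
bench$medianDsc
#> [1] 0.9765823
subset(bench$report@summary, cohort == "overall" & metric == "dsc")
#>     cohort metric  n    median      mean         sd sdDefined
#> 21 overall    dsc 40 0.9765823 0.9737932 0.01108586      TRUE
```

A median test Dice of ~0.977 means the predicted ICC masks overlap ground
truth almost voxel-for-voxel (1.0 = identical); the small SD across 40
phantoms from four differently contrasted cohorts is the desk-scale analogue
of cohort-robust performance. Individual pieces compose explicitly:

```r
spec <- deskCohortSpecs(nSubjects = 2)[[1]]   # cohort "A"
pair <- synthHead(spec, subjectIndex = 1)      # HeadVolume + ground-truth ICCMask
pmap <- predictProbmap(bench$state, pair$volume)
mask <- binarize(pmap, 0.34)                   # strict p > 0.34
dice(mask, pair$mask)
#> [1] 0.9821155
hausdorffMM(mask, pair$mask)                   # mm, exact via distance transforms
#> [1] 2
maskVolumeCm3(mask)                            # cm^3
#> [1] 15.864
```

A command-line wrapper over the same functions lives at `inst/cli/icc.R`
(subcommands `synth`, `preprocess`, `train`, `predict`, `calibrate`,
`evaluate`, `longitudinal`; TOML run configs).

## Package layout

| Where | What |
|---|---|
| `R/phantom.R` | cohort specs, subject geometry, phantom synthesis, datasets |
| `R/prep.R` | NIfTI I/O, auto-crop, normalisation, padding, native restore |
| `R/net.R` | architecture config, network construction, forward pass, checkpoints |
| `R/train.R` | sampler, loss, clipping, EMA, training loop |
| `R/infer.R` | probability maps, binarisation, threshold calibration, volumes |
| `R/metrics.R` | Dice, Hausdorff, FN/FP %, volume differences, reports |
| `R/harness.R` | diversity/stage/longitudinal experiments, desk benchmark |
| `src/ops.cpp` | conv/pool/upsample forward+backward, EDT, morphology |
| `vignettes/icc-segmentation-methods.Rmd` | model, assumptions, design notes |
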