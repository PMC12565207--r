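# msseg3d

CPU-only R framework for volumetric multiple sclerosis (MS) lesion
segmentation from multi-modal MRI (T1, T2, FLAIR).

MS lesions occupy roughly 0.3% of brain voxels, so a naive voxel classifier
collapses onto the background class. `msseg3d` implements the full pipeline
built around the two standard countermeasures:

* **Lesion-aware balanced patch sampling** — each training patch comes from a
  Bernoulli(0.5) mixture of lesion-centered and random crops, so the network
  sees lesions in half its patches instead of 0.3% of its voxels.
* **A compact inverted-bottleneck 3-D network** — *EfficientNet3D-UNet*, a
  U-Net whose encoder/decoder stages are MBConv3D blocks (1×1×1 expansion →
  depthwise 3×3×3 convolution → linear projection, Swish activations,
  residuals where shapes allow, trilinear upsampling in the decoder). The
  default build has ~0.19 M trainable parameters versus ~39 M for the
  bundled 3D U-Net baseline.

Training minimises the composite objective

    L = 0.7 * L_Dice + 0.3 * L_BCE

(squared-denominator soft Dice plus clipped binary cross-entropy) with Adam,
a cosine-annealed learning rate, early stopping on validation Dice, and
best-epoch checkpointing. Inference stitches overlapping sliding windows,
removes connected components below a voxel threshold ("small-blob
suppression"), and quantifies uncertainty by Monte-Carlo dropout (predictive
entropy of the mean over 30 stochastic passes) or a five-member deep
ensemble (voxel-wise variance), summarised by the expected calibration
error. The 3-D convolution/backprop engine is implemented in the package
itself (R + Rcpp, single-threaded, double precision) so everything is
bit-reproducible from one seed.

A synthetic phantom generator produces multi-modal cohorts — ellipsoidal
brains with sparse FLAIR/T2-hyperintense ellipsoidal lesions at a calibrated
0.29% voxel prevalence, bias fields and noise — in the exact six-file
subject layout the loaders expect, so the whole pipeline runs and is tested
without any external data.

## Worked example

```r
library(msseg3d)

## architecture sizes
spec <- networkSpec("efficientnet3d_unet")
net  <- buildNetwork(spec, seed = 0)
base <- buildNetwork(networkSpec("unet3d_baseline"), seed = 0)
countTrainableParameters(net)   # 190369
countTrainableParameters(base)  # 39059713

## a small synthetic cohort and its class imbalance
cfg <- phantomConfig(shape = c(48, 48, 48), lesion_radius_range = c(2, 4), seed = 1)
records <- generateCohort(7, cfg, "cohort")
masks <- lapply(records, function(r) binarize(readVolume(r$paths[["FLAIR_mask"]])))
lesionRatio(masks)$lesion_ratio_percent  # 0.306

## patient-level 70/15/15 split
ids <- vapply(records, function(r) r$subject_id, character(1))
split <- splitCohort(ids, seed = 1)     # 4 train / 1 val / 2 test

## balanced patch sampling on a preprocessed subject
s <- loadSubjectData(file.path("cohort", split$train_ids[1]))
stream <- balancedPatchStream(s, samplerConfig(patch_size = 16L, seed = 2))
p <- stream()
dim(p$image)        # 3 16 16 16
sum(p$mask)         # 124
p$lesion_centered   # TRUE
```

The printed numbers mean: the proposed network is ~205× smaller than the
baseline; the seven-subject phantom cohort pools to a 0.306% lesion ratio
(the generator targets 0.29%, the MS-cohort statistic, with stochastic
scatter); and the first draw of this stream took the lesion-centered branch,
so its 16³ mask contains a lesion (124 voxels) despite the ~0.3% background
prevalence.

Training, prediction, evaluation and uncertainty stages are available both
as functions (`trainModel()`, `slidingWindowPredict()`, `removeSmallBlobs()`,
`mcDropoutPredict()`, `ensemblePredict()`, `expectedCalibrationError()`) and
as a six-stage config-driven workflow (`cmdPhantom`, `cmdPreprocess`,
`cmdTrain`, `cmdPredict`, `cmdEvaluate`, `cmdUq`; thin CLI wrapper in
`inst/cli/msseg3d.R`). See the methods vignette
(`vignettes/msseg3d-methods.Rmd`) for the model, parameter and design
details.

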