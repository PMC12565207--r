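#' Small-blob suppression
#'
#' Removes connected components smaller than `min_voxels` from a binary
#' prediction — the post-processing step that suppresses small false-positive
#' blobs. Idempotent; monotone in `min_voxels` (larger thresholds yield
#' subset masks); `min_voxels = 0` is the identity.
#'
#' @param mask a [BinaryMask-class] (or plain \{0,1\} 3-D array).
#' @param min_voxels minimum surviving component size in voxels (default 5).
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return object of the same kind as `mask`, a subset of the input.
#' @export
removeSmallBlobs <- function(mask, min_voxels = 5L, connectivity = 26L) {
  if (min_voxels < 0) stop("min_voxels must be non-negative")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  arr <- if (is(mask, "BinaryMask")) volData(mask) else mask
  if (!all(arr %in% c(0, 1))) stop("mask must be binary")
  lab <- cpp_label_components(array(as.integer(arr), dim(arr)), dim(arr),
                              as.integer(connectivity))
  keep <- which(lab$sizes >= min_voxels)
  out <- array(0, dim(arr))
  out[lab$labels %in% keep & arr == 1] <- 1
  if (is(mask, "BinaryMask")) BinaryMask(out, voxelSpacing(mask)) else out
}

#' Binary predictive entropy
#'
#' `-(p*log(p) + (1-p)*log(1-p))` in nats, with `0 * log(0)` defined as 0.
#' Maximal (`ln 2`) at `p = 0.5`, zero at `p` in \{0, 1\}.
#'
#' @param p probabilities in [0, 1] (any shape).
#' @return entropy field of the same shape.
#' @export
binaryEntropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  term <- function(q) ifelse(q > 0, q * log(q), 0)
  h <- -(term(p) + term(1 - p))
  h[h < 0] <- 0 # guard tiny negative rounding
  h
}

#' Monte-Carlo dropout prediction
#'
#' Keeps the spatial dropout layers active at inference and averages
#' `n_passes` stochastic sliding-window probability fields; the voxel-wise
#' uncertainty is the binary predictive entropy of the mean probability.
#' The study protocol uses dropout p = 0.25 and 30 passes.
#'
#' @param net network from [buildNetwork()]; must contain dropout layers.
#' @param volume a [MultiModalVolume-class].
#' @param n_passes number of stochastic passes (>= 2).
#' @param patch_size,overlap sliding-window parameters.
#' @param seed integer seed for the dropout draws.
#' @return an [UncertaintyMap-class] (`method = "mc_dropout"`).
#' @export
mcDropoutPredict <- function(net, volume, n_passes = 30L, patch_size = 64L,
                             overlap = 0.5, seed = 0L) {
  stopifnot(n_passes >= 2L)
  layers <- netLayers(net)
  has_drop <- any(vapply(layers, function(l) identical(l$type, "dropout3d"),
                         logical(1)))
  if (!has_drop)
    stop("network has no dropout layers; MC-dropout prediction is meaningless")
  shape <- dim(mmChannels(volume))[-1]
  acc <- array(0, shape)
  withSeed(seed, {
    for (k in seq_len(n_passes)) {
      pv <- slidingWindowPredict(net, volume, patch_size, overlap, mc = TRUE)
      acc <- acc + volData(pv)
    }
  })
  mp <- acc / n_passes
  mp[mp < 0] <- 0; mp[mp > 1] <- 1
  new("UncertaintyMap", meanProb = mp, uncertainty = binaryEntropy(mp),
      method = "mc_dropout", nSamples = as.integer(n_passes))
}

#' Deep-ensemble prediction
#'
#' Mean and population variance of the member probability fields; the
#' variance is the voxel-wise uncertainty estimate.
#'
#' @param checkpoints list of checkpoints from [trainModel()] /
#'   [trainEnsemble()] (each with `spec` and `state`), or a list of built
#'   networks.
#' @param volume a [MultiModalVolume-class].
#' @param patch_size,overlap sliding-window parameters.
#' @return an [UncertaintyMap-class] (`method = "ensemble"`).
#' @export
ensemblePredict <- function(checkpoints, volume, patch_size = 64L,
                            overlap = 0.5) {
  stopifnot(length(checkpoints) >= 2L)
  nets <- lapply(checkpoints, function(ck) {
    if (is.environment(ck)) return(ck)
    if (is.null(ck$spec) || is.null(ck$state))
      stop("checkpoint must carry spec and state")
    net <- buildNetwork(ck$spec, seed = 0L)
    loadStateDict(net, ck$state)
    net
  })
  specs <- lapply(nets, function(n) unclass(n$spec))
  if (!all(vapply(specs[-1], identical, logical(1), y = specs[[1]])))
    stop("ensemble members have mismatched network specs")
  shape <- dim(mmChannels(volume))[-1]
  s1 <- array(0, shape)
  s2 <- array(0, shape)
  for (net in nets) {
    p <- volData(slidingWindowPredict(net, volume, patch_size, overlap))
    s1 <- s1 + p
    s2 <- s2 + p^2
  }
  n <- length(nets)
  mp <- s1 / n
  v <- s2 / n - mp^2
  v[v < 0] <- 0
  mp[mp < 0] <- 0; mp[mp > 1] <- 1
  new("UncertaintyMap", meanProb = mp, uncertainty = v,
      method = "ensemble", nSamples = as.integer(n))
}

#' Expected calibration error and uncertainty-error association
#'
#' Confidence is the max-probability `max(p, 1 - p)`; voxels are pooled into
#' `n_bins` equal-width confidence bins over [0, 1] and
#' `ECE = sum_b (n_b / N) * |acc_b - conf_b|`. Also reports the Pearson
#' (point-biserial) correlation between a voxel-wise uncertainty field
#' (default: binary entropy of `probs`) and the misclassification indicator.
#'
#' @param probs probability field in [0, 1].
#' @param labels \{0,1\} field of the same shape.
#' @param n_bins number of equal-width confidence bins (default 10).
#' @param uncertainty optional uncertainty field matching `probs`.
#' @return a `CalibrationReport`: list with `ece`, `bin_edges`, `bins`
#'   (per-bin confidence/accuracy/count) and `unc_error_correlation`.
#' @export
expectedCalibrationError <- function(probs, labels, n_bins = 10L,
                                     uncertainty = NULL) {
  p <- as.numeric(probs)
  y <- as.numeric(labels)
  if (!length(p)) stop("empty input")
  if (length(p) != length(y)) stop("probs and labels differ in length")
  if (any(p < 0 | p > 1)) stop("probs must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  conf <- pmax(p, 1 - p)
  pred <- as.numeric(p > 0.5)
  correct <- as.numeric(pred == y)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(conf, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  nb <- tabulate(bin, n_bins)
  accb <- confb <- rep(NA_real_, n_bins)
  occupied <- which(nb > 0)
  for (b in occupied) {
    sel <- bin == b
    accb[b] <- mean(correct[sel])
    confb[b] <- mean(conf[sel])
  }
  ece <- sum(nb[occupied] / length(p) * abs(accb[occupied] - confb[occupied]))
  unc <- if (is.null(uncertainty)) binaryEntropy(p) else as.numeric(uncertainty)
  err <- 1 - correct
  corr <- if (sd(unc) > 0 && sd(err) > 0) cor(unc, err) else NA_real_
  structure(list(ece = ece, bin_edges = edges,
                 bins = data.frame(bin = seq_len(n_bins), count = nb,
                                   confidence = confb, accuracy = accb),
                 unc_error_correlation = corr),
            class = "CalibrationReport")
}

#' Write an uncertainty map as NIfTI
#'
#' Mean-probability and uncertainty fields are written alongside each other.
#'
#' @param umap an [UncertaintyMap-class].
#' @param prefix output path prefix; writes `<prefix>_mean.nii.gz` and
#'   `<prefix>_uncertainty.nii.gz`.
#' @param spacing voxel spacing (mm).
#' @export
writeUncertaintyMap <- function(umap, prefix, spacing = c(1, 1, 1)) {
  writeVolume(VolumeGrid(meanProb(umap), spacing),
              paste0(prefix, "_mean.nii.gz"))
  writeVolume(VolumeGrid(uncertaintyField(umap), spacing),
              paste0(prefix, "_uncertainty.nii.gz"))
  invisible(prefix)
}
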