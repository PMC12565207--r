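# Shared fixtures: tiny phantom configs, reduced network specs, a per-subject
# normalisation helper, and the pure-R flood-fill oracle used to validate the
# connected-component kernel.

tinyPhantomConfig <- function(shape = c(32, 32, 32), seed = 0L, ...) {
  phantomConfig(shape = shape, lesion_radius_range = c(2, 3),
                n_lesions_range = c(1, 20), seed = seed, ...)
}

tinyNetSpec <- function(dropout_rate = 0.25) {
  networkSpec("efficientnet3d_unet", stem_channels = 6L,
              encoder_channels = c(6L, 8L, 10L, 12L),
              bottleneck_channels = 16L,
              decoder_channels = c(12L, 10L, 8L, 6L),
              dropout_rate = dropout_rate)
}

reducedNetSpec <- function(dropout_rate = 0.25) {
  networkSpec("efficientnet3d_unet", stem_channels = 8L,
              encoder_channels = c(8L, 12L, 16L, 24L),
              bottleneck_channels = 48L,
              decoder_channels = c(32L, 24L, 16L, 12L),
              dropout_rate = dropout_rate)
}

# z-score normalise each modality of a phantom subject in place
normalizeSubject <- function(s) {
  ch <- mmChannels(s$volume)
  sp <- dim(ch)[-1]
  for (m in 1:3)
    ch[m, , , ] <- volData(zscoreNormalize(VolumeGrid(array(ch[m, , , ], sp))))
  list(volume = MultiModalVolume(ch, voxelSpacing(s$volume)), mask = s$mask)
}

# one lesioned patch with FLAIR/T2-hyperintense, T1-hypointense blob
makeLesionPatch <- function(s = 16L, seed = 7) {
  set.seed(seed)
  msk <- array(0, c(s, s, s))
  lo <- s %/% 2 - 1; hi <- s %/% 2 + 2
  msk[lo:hi, lo:hi, lo:hi] <- 1
  img <- array(rnorm(3 * s^3, sd = 0.1), c(3, s, s, s))
  shift <- c(-0.5, 1.5, 2)
  for (m in 1:3) img[m, , , ] <- img[m, , , ] + shift[m] * msk
  structure(list(image = img, mask = msk, origin = c(0L, 0L, 0L),
                 lesion_centered = TRUE), class = "Patch")
}

# Independent flood-fill connected-component oracle (pure R, BFS).
floodFillComponents <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dd = -1:1, dh = -1:1, dw = -1:1)
  offs <- offs[!(offs$dd == 0 & offs$dh == 0 & offs$dw == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dd) + abs(offs$dh) + abs(offs$dw) == 1, ]
  labels <- array(0L, d)
  nextlab <- 0L
  sizes <- integer(0)
  for (start in which(mask == 1 & labels == 0)) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    size <- 0L
    while (length(queue)) {
      idx <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      pos <- arrayInd(idx, d)
      for (r in seq_len(nrow(offs))) {
        p <- pos + c(offs$dd[r], offs$dh[r], offs$dw[r])
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[j] == 1 && labels[j] == 0L) {
          labels[j] <- nextlab
          queue <- c(queue, j)
        }
      }
    }
    sizes[nextlab] <- size
  }
  list(labels = labels, sizes = sizes)
}

# reference blob filter built on the oracle
oracleRemoveSmall <- function(mask, min_voxels, connectivity) {
  cc <- floodFillComponents(mask, connectivity)
  out <- array(0, dim(mask))
  keep <- which(cc$sizes >= min_voxels)
  out[cc$labels %in% keep & mask == 1] <- 1
  out
}
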