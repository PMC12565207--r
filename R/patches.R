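#' Balanced patch-sampler configuration
#'
#' @param patch_size cubic patch side in voxels (default 64, the training
#'   patch size; must be at least 8).
#' @param p_lesion probability that a draw takes the lesion-centered branch
#'   (default 0.5, the balanced 50/50 sampling that counters the ~0.29%
#'   voxel-level class imbalance).
#' @param seed integer seed of the patch stream.
#' @return a `SamplerConfig` list.
#' @export
samplerConfig <- function(patch_size = 64L, p_lesion = 0.5, seed = 0L) {
  stopifnot(patch_size >= 8, p_lesion >= 0, p_lesion <= 1)
  structure(list(patch_size = as.integer(patch_size), p_lesion = p_lesion,
                 seed = as.integer(seed)),
            class = "SamplerConfig")
}

#' Training-time augmentation configuration
#'
#' One sampled transform chain per patch: per-axis flips, a single affine
#' (scaling by +/-10%, rotation by +/-10 degrees about a random axis,
#' translation by +/-5 voxels), additive low-variance Gaussian noise on the
#' image only, and a multiplicative bias field on the image only. Geometric
#' transforms are applied identically to all three channels and the mask
#' (linear interpolation for the image, nearest for the mask); augmentations
#' are disabled for validation/test streams.
#'
#' @param flip_prob per-axis flip probability.
#' @param scale_range fractional scale half-range (default 0.10).
#' @param rot_range rotation half-range in degrees (default 10).
#' @param translate_range translation half-range in voxels (default 5).
#' @param noise_sd additive Gaussian noise sd in normalised units
#'   (default 0.03).
#' @param bias_amplitude multiplicative bias-field amplitude.
#' @param enabled master switch; `FALSE` for validation/test streams.
#' @return an `AugmentConfig` list.
#' @export
augmentConfig <- function(flip_prob = 0.5, scale_range = 0.10, rot_range = 10,
                          translate_range = 5, noise_sd = 0.03,
                          bias_amplitude = 0.10, enabled = TRUE) {
  stopifnot(flip_prob >= 0, flip_prob <= 1, scale_range >= 0, rot_range >= 0,
            translate_range >= 0, noise_sd >= 0, bias_amplitude >= 0)
  structure(list(flip_prob = flip_prob, scale_range = scale_range,
                 rot_range = rot_range, translate_range = translate_range,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 enabled = isTRUE(enabled)),
            class = "AugmentConfig")
}

#' Draw a patch centre
#'
#' If `lesion_centered` and the mask has at least one lesion voxel, the
#' centre is a uniformly chosen lesion voxel; otherwise a uniformly chosen
#' non-lesion voxel. The centre is then clamped so a full patch window fits
#' inside the volume (the drawn voxel stays inside the patch, though not
#' necessarily at its exact centre). Requesting a lesion centre on an
#' all-zero mask falls back to a random centre with a warning. Consumes the
#' current RNG stream.
#'
#' @param mask a [BinaryMask-class].
#' @param lesion_centered logical branch flag.
#' @param patch_size patch side in voxels.
#' @return integer (d, h, w) 0-based clamped centre, with attribute `drawn`
#'   holding the pre-clamp voxel.
#' @export
sampleCenter <- function(mask, lesion_centered, patch_size) {
  m <- volData(mask)
  shape <- dim(m)
  if (lesion_centered && !any(m == 1)) {
    warning("lesion-centered draw requested on an all-zero mask; falling back to a random centre")
    lesion_centered <- FALSE
  }
  pool <- if (lesion_centered) which(m == 1) else which(m == 0)
  if (!length(pool)) pool <- seq_len(prod(shape)) # mask all ones, degenerate
  v <- arrayInd(pool[sample.int(length(pool), 1L)], shape) - 1L
  v <- as.integer(v)
  half <- patch_size %/% 2L
  lo <- half
  hi <- pmax(lo, shape - (patch_size - half) ) # last valid centre per axis
  ctr <- pmin(pmax(v, lo), hi)
  attr(ctr, "drawn") <- v
  ctr
}

#' Extract an aligned image/mask patch
#'
#' Cuts the half-open window `[start, start + size)` with
#' `start = center - size %/% 2`, clamped so the window fits; when the volume
#' is smaller than the patch the missing voxels are zero-padded.
#'
#' @param volume a [MultiModalVolume-class].
#' @param mask aligned [BinaryMask-class].
#' @param center integer (d, h, w) 0-based centre.
#' @param patch_size patch side in voxels.
#' @return a `Patch`: list with `image` [3, s, s, s], `mask` [s, s, s],
#'   `origin` (0-based window start) and `lesion_centered` (filled by the
#'   stream).
#' @export
extractPatch <- function(volume, mask, center, patch_size) {
  ch <- mmChannels(volume)
  m <- volData(mask)
  shape <- dim(m)
  s <- as.integer(patch_size)
  start <- as.integer(center) - s %/% 2L
  start <- pmin(pmax(start, 0L), pmax(shape - s, 0L))
  img <- array(0, c(3L, s, s, s))
  msk <- array(0, c(s, s, s))
  n <- pmin(s, shape - start) # voxels available per axis
  src <- lapply(seq_len(3), function(a) start[a] + seq_len(n[a]))
  dst <- lapply(seq_len(3), function(a) seq_len(n[a]))
  img[, dst[[1]], dst[[2]], dst[[3]]] <- ch[, src[[1]], src[[2]], src[[3]], drop = FALSE]
  msk[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  structure(list(image = img, mask = msk, origin = start,
                 lesion_centered = NA),
            class = "Patch")
}

# Rotation matrix about array axis `axis` (1=D, 2=H, 3=W) by theta radians.
rotAxis <- function(axis, theta) {
  c3 <- cos(theta); s3 <- sin(theta)
  R <- diag(3)
  oth <- setdiff(1:3, axis)
  R[oth[1], oth[1]] <- c3; R[oth[2], oth[2]] <- c3
  R[oth[1], oth[2]] <- -s3; R[oth[2], oth[1]] <- s3
  R
}

#' Apply the augmentation chain to a patch
#'
#' Draws one transform chain from `config` and applies it: per-axis flips
#' (probability `flip_prob` each), one affine (scale, single-axis rotation,
#' translation; linear interpolation for the image, nearest for the mask,
#' out-of-field voxels filled with 0), additive Gaussian noise and a
#' multiplicative bias field on the image only. The identical geometric
#' transform is applied to all three channels and the mask; the mask stays
#' binary and is bit-identical under the image-only degradations. With all
#' probabilities and ranges zero the patch is returned unchanged. Consumes
#' the current RNG stream.
#'
#' @param patch a `Patch`.
#' @param config an `AugmentConfig`.
#' @return augmented `Patch`.
#' @export
applyAugmentations <- function(patch, config) {
  if (!config$enabled) return(patch)
  img <- patch$image
  msk <- patch$mask
  # anatomical-plane flips on RAS-canonical axes: axial<->D, coronal<->H,
  # sagittal<->W
  if (config$flip_prob > 0) {
    for (a in 1:3) {
      if (runif(1) < config$flip_prob) {
        img <- flipAxis(img, a)
        msk <- flipAxis(msk, a)
      }
    }
  }
  if (config$scale_range > 0 || config$rot_range > 0 || config$translate_range > 0) {
    sc <- runif(1, 1 - config$scale_range, 1 + config$scale_range)
    axis <- sample.int(3L, 1L)
    theta <- runif(1, -config$rot_range, config$rot_range) * pi / 180
    tr <- runif(3, -config$translate_range, config$translate_range)
    A <- rotAxis(axis, theta) * sc
    M <- solve(A)                       # inverse map: output -> input
    toff <- -as.numeric(M %*% tr)
    img <- cpp_affine_resample(img, dim(img), M, toff, 0L)
    m4 <- array(msk, c(1L, dim(msk)))
    m4 <- cpp_affine_resample(m4, dim(m4), M, toff, 1L)
    msk <- array(m4, dim(msk))
  }
  if (config$noise_sd > 0)
    img <- img + array(rnorm(length(img), sd = config$noise_sd), dim(img))
  if (config$bias_amplitude > 0) {
    f <- biasField(dim(msk), config$bias_amplitude)
    for (ci in 1:3) img[ci, , , ] <- img[ci, , , ] * f
  }
  patch$image <- img
  patch$mask <- msk
  patch
}

#' Reproducible balanced patch stream
#'
#' Returns a closure producing one `Patch` per call. Each draw flips a
#' Bernoulli(`p_lesion`) coin to choose the lesion-centered branch versus a
#' random (non-lesion-conditioned) centre, extracts the window, and applies
#' augmentation when an enabled `AugmentConfig` is given. The stream owns a
#' private RNG state seeded from `sampler_config$seed`, so two streams with
#' the same seed yield identical patch sequences regardless of surrounding
#' RNG use.
#'
#' @param subject a `PhantomSubject` or any list with `volume`
#'   ([MultiModalVolume-class]) and `mask` ([BinaryMask-class]).
#' @param sampler_config a `SamplerConfig`.
#' @param augment_config optional `AugmentConfig` (NULL or disabled =>
#'   no augmentation, as for validation/test streams).
#' @return function() -> `Patch` with the branch recorded in
#'   `$lesion_centered`.
#' @export
balancedPatchStream <- function(subject, sampler_config, augment_config = NULL) {
  stream <- rngStream(sampler_config$seed)
  function() {
    stream({
      branch <- runif(1) < sampler_config$p_lesion
      ctr <- sampleCenter(subject$mask, branch, sampler_config$patch_size)
      p <- extractPatch(subject$volume, subject$mask, ctr,
                        sampler_config$patch_size)
      p$lesion_centered <- branch
      if (!is.null(augment_config) && augment_config$enabled)
        p <- applyAugmentations(p, augment_config)
      p
    })
  }
}
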