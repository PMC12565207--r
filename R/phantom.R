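#' Phantom cohort configuration
#'
#' Parameters of the synthetic multi-modal MS-like brain phantom. Defaults
#' emulate the statistics of a consensus-segmented MS cohort: sparse
#' (target prevalence 0.29% of grid voxels), scattered, anisotropic
#' ellipsoidal lesions that are hyperintense on FLAIR/T2 and slightly
#' hypointense on T1, inside an ellipsoidal "brain" on a zero background,
#' degraded by a smooth multiplicative bias field and additive Gaussian
#' noise.
#'
#' @param shape grid size (D, H, W) in voxels; default 96^3 so several 64^3
#'   patches fit and CPU runtimes stay in seconds.
#' @param target_prevalence target lesion fraction of total grid voxels
#'   (default 0.0029).
#' @param n_lesions_range (min, max) lesion count per subject.
#' @param lesion_radius_range (min, max) per-axis ellipsoid radii in voxels.
#' @param tissue_means per-modality named list of background/brain/lesion
#'   intensity means; FLAIR and T2 lesion means exceed brain means, T1 lesion
#'   mean does not.
#' @param noise_sd additive Gaussian noise sd in normalised intensity units.
#' @param bias_amplitude amplitude of the multiplicative bias field
#'   (fractional deviation from 1).
#' @param seed base integer seed; subject `k` of a cohort uses `seed + k - 1`.
#' @return a `PhantomConfig` list.
#' @export
phantomConfig <- function(shape = c(96, 96, 96),
                          target_prevalence = 0.0029,
                          n_lesions_range = c(1, 80),
                          lesion_radius_range = c(2, 6),
                          tissue_means = list(
                            T1 = c(background = 0, brain = 0.70, lesion = 0.55),
                            T2 = c(background = 0, brain = 0.50, lesion = 0.80),
                            FLAIR = c(background = 0, brain = 0.50, lesion = 0.90)),
                          noise_sd = 0.02,
                          bias_amplitude = 0.20,
                          seed = 0L) {
  stopifnot(length(shape) == 3L, all(shape >= 8),
            target_prevalence > 0, target_prevalence < 1,
            lesion_radius_range[1] >= 1,
            lesion_radius_range[2] >= lesion_radius_range[1],
            n_lesions_range[1] >= 1, n_lesions_range[2] >= n_lesions_range[1],
            noise_sd >= 0, bias_amplitude >= 0, bias_amplitude < 1)
  if (any(shape < 4 * lesion_radius_range[1]))
    stop("grid too small to contain one lesion")
  structure(list(shape = as.integer(shape),
                 target_prevalence = target_prevalence,
                 n_lesions_range = as.integer(n_lesions_range),
                 lesion_radius_range = lesion_radius_range,
                 tissue_means = tissue_means,
                 noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

# Smooth order-3 multiplicative bias field: 1 + amplitude * g where g is a
# random polynomial in centred coordinates, shifted to mean 0 and scaled to
# max |g| = 1. Guarantees field mean 1 and max/min ratio bounded by
# (1 + a) / (1 - a).
biasField <- function(shape, amplitude) {
  if (amplitude <= 0) return(array(1, shape))
  ax <- lapply(shape, function(n) if (n == 1L) 0 else seq(-1, 1, length.out = n))
  g <- array(0, shape)
  for (i in 0:3) for (j in 0:3) for (k in 0:3) {
    if (i + j + k == 0 || i + j + k > 3) next
    coef <- runif(1, -1, 1)
    g <- g + coef * outer(outer(ax[[1]]^i, ax[[2]]^j), ax[[3]]^k)
  }
  g <- g - mean(g)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  1 + amplitude * g
}

#' Generate the brain background of a phantom subject
#'
#' Places an ellipsoidal "brain" of per-modality brain-mean intensity inside
#' a zero background. The ellipsoid semi-axes are drawn around 42% of each
#' grid dimension, giving a brain volume fraction of roughly 0.3. Noise and
#' bias degradations are applied later by [renderModalities()]. Consumes the
#' current RNG stream; deterministic given the RNG state.
#'
#' @param config a `PhantomConfig`.
#' @return list with `volume` ([MultiModalVolume-class]) and `brain_region`
#'   ([BinaryMask-class]).
#' @export
makeBrainBackground <- function(config) {
  shape <- config$shape
  semi <- runif(3, 0.40, 0.44) * shape
  ctr <- (shape - 1) / 2
  ax <- lapply(seq_len(3), function(a) ((seq_len(shape[a]) - 1) - ctr[a]) / semi[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  brain <- (r2 <= 1) * 1
  if (!any(brain == 1)) stop("grid too small for a brain ellipsoid")
  channels <- array(0, c(3, shape))
  for (m in seq_len(3)) {
    mod <- c("T1", "T2", "FLAIR")[m]
    channels[m, , , ] <- brain * config$tissue_means[[mod]][["brain"]]
  }
  list(volume = MultiModalVolume(channels),
       brain_region = BinaryMask(brain))
}

#' Place random ellipsoidal lesions inside the brain
#'
#' Adds axis-aligned anisotropic ellipsoids at uniformly drawn centres fully
#' inside the brain region until the achieved prevalence (relative to total
#' grid voxels) first reaches or exceeds the target, or the maximum lesion
#' count is hit. When the remaining voxel budget is small, radii are capped
#' so the stopping overshoot stays bounded. Consumes the current RNG stream.
#'
#' @param brain_region [BinaryMask-class] from [makeBrainBackground()].
#' @param config a `PhantomConfig`.
#' @return lesion [BinaryMask-class] (subset of the brain region).
#' @export
placeLesions <- function(brain_region, config) {
  brain <- volData(brain_region)
  shape <- dim(brain)
  total <- prod(shape)
  target <- config$target_prevalence * total
  rmin <- config$lesion_radius_range[1]
  rmax <- config$lesion_radius_range[2]
  if (2 * rmax >= min(shape)) stop("lesion radius too large for the grid")
  lesions <- array(0, shape)
  brain_idx <- which(brain == 1)
  n <- 0L
  count <- 0
  while ((count < target || n < config$n_lesions_range[1]) &&
         n < config$n_lesions_range[2]) {
    remaining <- max(target - count, 0)
    # cap radii so a single lesion cannot vastly overshoot the budget
    rcap <- rmax
    if (remaining > 0) {
      r_budget <- (3 * 1.5 * remaining / (4 * pi))^(1 / 3)
      rcap <- max(rmin, min(rmax, r_budget))
    }
    radii <- runif(3, rmin, rcap)
    placed <- FALSE
    for (attempt in seq_len(50)) {
      ci <- arrayInd(sample(brain_idx, 1), shape)
      ctr <- as.numeric(ci - 1L)
      # require the six axis-extreme voxels inside the brain
      ok <- TRUE
      for (a in seq_len(3)) for (s in c(-1, 1)) {
        p <- pmin(shape - 1, pmax(0, round(ctr + s * radii * (seq_len(3) == a))))
        if (brain[p[1] + 1, p[2] + 1, p[3] + 1] != 1) { ok <- FALSE; break }
      }
      if (!ok) next
      rng <- lapply(seq_len(3), function(a) {
        lo <- max(0, floor(ctr[a] - radii[a]))
        hi <- min(shape[a] - 1, ceiling(ctr[a] + radii[a]))
        seq(lo, hi)
      })
      dsq <- outer(outer(((rng[[1]] - ctr[1]) / radii[1])^2,
                         ((rng[[2]] - ctr[2]) / radii[2])^2, `+`),
                   ((rng[[3]] - ctr[3]) / radii[3])^2, `+`)
      blob <- (dsq <= 1) * 1
      sub <- lesions[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1]
      bsub <- brain[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1]
      lesions[rng[[1]] + 1, rng[[2]] + 1, rng[[3]] + 1] <-
        pmax(sub, blob * bsub)
      placed <- TRUE
      break
    }
    if (!placed) break
    n <- n + 1L
    count <- sum(lesions)
  }
  BinaryMask(lesions, voxelSpacing(brain_region))
}

#' Render the modality intensities of a phantom subject
#'
#' Paints lesion voxels with per-modality lesion means (FLAIR/T2 hyperintense,
#' T1 hypo/isointense relative to brain), applies an independent smooth
#' multiplicative bias field per modality, and adds Gaussian noise inside the
#' brain (the zero background is left exactly zero so that the non-zero-voxel
#' normalisation convention holds downstream). Consumes the current RNG
#' stream.
#'
#' @param background list from [makeBrainBackground()].
#' @param lesions lesion [BinaryMask-class].
#' @param config a `PhantomConfig`.
#' @return a [MultiModalVolume-class].
#' @export
renderModalities <- function(background, lesions, config) {
  channels <- mmChannels(background$volume)
  brain <- volData(background$brain_region)
  les <- volData(lesions)
  shape <- dim(brain)
  for (m in seq_len(3)) {
    mod <- c("T1", "T2", "FLAIR")[m]
    ch <- channels[m, , , ]
    dim(ch) <- shape
    ch[les == 1] <- config$tissue_means[[mod]][["lesion"]]
    ch <- ch * biasField(shape, config$bias_amplitude)
    if (config$noise_sd > 0) {
      noise <- array(rnorm(prod(shape), sd = config$noise_sd), shape)
      ch <- ch + noise * brain
    }
    ch[brain == 0] <- 0
    channels[m, , , ] <- ch
  }
  MultiModalVolume(channels, voxelSpacing(background$volume))
}

#' Generate one phantom subject
#'
#' Deterministic given `config$seed` (plus `index - 1`).
#'
#' @param config a `PhantomConfig`.
#' @param index 1-based subject index within a cohort; offsets the seed.
#' @return a `PhantomSubject`: list with `volume`, `mask`,
#'   `achieved_prevalence`, `n_lesions`, `seed`.
#' @export
generateSubject <- function(config, index = 1L) {
  seed <- config$seed + as.integer(index) - 1L
  withSeed(seed, {
    bg <- makeBrainBackground(config)
    mask <- placeLesions(bg$brain_region, config)
    vol <- renderModalities(bg, mask, config)
    comps <- cpp_label_components(array(as.integer(volData(mask)),
                                        dim(volData(mask))),
                                  dim(volData(mask)), 26L)
    structure(list(volume = vol, mask = mask,
                   brain_region = bg$brain_region,
                   achieved_prevalence = sum(volData(mask)) / prod(config$shape),
                   n_lesions = length(comps$sizes),
                   seed = seed),
              class = "PhantomSubject")
  })
}

#' Generate and write a phantom cohort
#'
#' Writes `n` subjects in the exact directory layout [validateSubject()]
#' expects (`sub-001/…/FLAIR_mask.nii.gz`, the three modality masks being
#' identical copies of the consensus mask), plus a CSV manifest
#' (subject_id, achieved_prevalence, seed). Subject ids are zero-padded with
#' stable ordering; generation is bit-reproducible given `(n, config$seed)`.
#'
#' @param n number of subjects.
#' @param config a `PhantomConfig`.
#' @param out_dir writable output directory.
#' @return list of `SubjectRecord` (one per subject, already validated).
#' @export
generateCohort <- function(n, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(subject_id = character(0),
                         achieved_prevalence = numeric(0),
                         n_lesions = integer(0), seed = integer(0))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- generateSubject(config, index = i)
    id <- sprintf("sub-%03d", i)
    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    ch <- mmChannels(subj$volume)
    sp <- voxelSpacing(subj$volume)
    for (m in seq_len(3)) {
      mod <- c("T1", "T2", "FLAIR")[m]
      arr <- ch[m, , , ]
      dim(arr) <- dim(ch)[-1]
      writeVolume(VolumeGrid(arr, sp), file.path(sdir, paste0(mod, ".nii.gz")))
      writeVolume(subj$mask, file.path(sdir, paste0(mod, "_mask.nii.gz")))
    }
    manifest <- rbind(manifest, data.frame(
      subject_id = id, achieved_prevalence = subj$achieved_prevalence,
      n_lesions = subj$n_lesions, seed = subj$seed))
    records[[i]] <- validateSubject(sdir)
  }
  write.table(manifest, file.path(out_dir, "manifest.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  records
}
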