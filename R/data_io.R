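#' Read a NIfTI volume
#'
#' Loads a NIfTI-1/-2 file, reorients the array to the closest-to-RAS axis
#' order so that flips and patch axes have a stable anatomical meaning across
#' files, and returns a [VolumeGrid-class] carrying the header voxel spacing.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [VolumeGrid-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to parse NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code > 0 || hdr$sform_code > 0)
    RNifti::orientation(img) <- "RAS"
  sp <- RNifti::pixdim(img)[seq_len(3)]
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  VolumeGrid(arr, sp)
}

#' Write a volume or mask as NIfTI
#'
#' Data are stored as 32-bit float, which round-trips float32-representable
#' values bit-exactly.
#'
#' @param x a [VolumeGrid-class] or [BinaryMask-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  arr <- volData(x)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxelSpacing(x)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Default subject-directory filename roles
#'
#' The expected six-file layout of one subject directory:
#' T1, T2 and FLAIR volumes plus one lesion mask per modality.
#' @export
subjectFilePatterns <- function() {
  c(T1 = "T1.nii.gz", T2 = "T2.nii.gz", FLAIR = "FLAIR.nii.gz",
    T1_mask = "T1_mask.nii.gz", T2_mask = "T2_mask.nii.gz",
    FLAIR_mask = "FLAIR_mask.nii.gz")
}

#' Validate a subject directory
#'
#' Programmatically inspects one subject directory for the six required NIfTI
#' files (three modalities plus the three modality lesion masks) and checks
#' that each parses as NIfTI. Subjects failing validation raise an error that
#' names every missing or unreadable role, so cohort-level validation can
#' report rather than silently drop them.
#'
#' @param directory subject directory.
#' @param patterns named character vector of filename patterns per role; see
#'   [subjectFilePatterns()].
#' @return a `SubjectRecord`: list with `subject_id` and the six resolved
#'   paths.
#' @export
validateSubject <- function(directory, patterns = subjectFilePatterns()) {
  if (!dir.exists(directory)) stop("subject directory not found: ", directory)
  roles <- names(patterns)
  paths <- file.path(directory, patterns)
  names(paths) <- roles
  bad <- character(0)
  for (r in roles) {
    if (!file.exists(paths[[r]])) {
      bad <- c(bad, paste0(r, " (missing)"))
    } else {
      ok <- tryCatch({ RNifti::niftiHeader(paths[[r]]); TRUE },
                     error = function(e) FALSE)
      if (!ok) bad <- c(bad, paste0(r, " (unreadable)"))
    }
  }
  if (length(bad))
    stop("subject '", basename(directory), "' failed validation: ",
         paste(bad, collapse = ", "))
  structure(list(subject_id = basename(directory), paths = paths),
            class = "SubjectRecord")
}

#' Validate a cohort directory
#'
#' Applies [validateSubject()] to every sub-directory of `root`. Failures are
#' collected and reported, not silently dropped.
#'
#' @param root directory whose sub-directories are subjects.
#' @return list with `records` (valid `SubjectRecord`s) and `failures`
#'   (named character vector of validation messages).
#' @export
validateCohort <- function(root) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  records <- list(); failures <- character(0)
  for (d in dirs) {
    rec <- tryCatch(validateSubject(d), error = function(e) e)
    if (inherits(rec, "error")) failures[basename(d)] <- conditionMessage(rec)
    else records[[basename(d)]] <- rec
  }
  if (length(failures))
    warning(length(failures), " subject(s) failed validation: ",
            paste(names(failures), collapse = ", "))
  list(records = records, failures = failures)
}

#' Resample a volume onto a reference grid
#'
#' Shape-based resampling used to align modalities: linear interpolation for
#' continuous intensity volumes, nearest-neighbour for binary lesion masks
#' (which therefore stay binary). Coordinates are mapped corner-to-corner
#' (index `i` of the output maps to `i * (n_in - 1) / (n_out - 1)`), so a
#' volume already on the reference grid is returned unchanged.
#'
#' @param moving [VolumeGrid-class] or [BinaryMask-class] to resample.
#' @param reference [VolumeGrid-class] providing the target shape/spacing.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return object of the same class as `moving`, on the reference grid.
#' @export
resampleLike <- function(moving, reference, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  x <- volData(moving)
  din <- dim(x)
  dout <- dim(volData(reference))
  coords <- lapply(seq_len(3), function(a) {
    if (dout[a] == 1L) rep(0, 1)
    else (seq_len(dout[a]) - 1) * (din[a] - 1) / (dout[a] - 1)
  })
  if (interpolation == "nearest") {
    idx <- lapply(seq_len(3), function(a) pmin(din[a], pmax(1L, as.integer(round(coords[[a]])) + 1L)))
    out <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- dout
  } else {
    lo <- lapply(seq_len(3), function(a) pmin(din[a] - 1L, pmax(0L, as.integer(floor(coords[[a]])))))
    fr <- lapply(seq_len(3), function(a) {
      if (din[a] == 1L) rep(0, dout[a]) else coords[[a]] - lo[[a]]
    })
    hi <- lapply(seq_len(3), function(a) pmin(din[a] - 1L, lo[[a]] + 1L))
    out <- array(0, dout)
    for (bw in 0:1) for (bh in 0:1) for (bd in 0:1) {
      wt <- outer(outer(if (bd) fr[[1]] else 1 - fr[[1]],
                        if (bh) fr[[2]] else 1 - fr[[2]]),
                  if (bw) fr[[3]] else 1 - fr[[3]])
      id <- (if (bd) hi[[1]] else lo[[1]]) + 1L
      ih <- (if (bh) hi[[2]] else lo[[2]]) + 1L
      iw <- (if (bw) hi[[3]] else lo[[3]]) + 1L
      out <- out + wt * x[id, ih, iw, drop = FALSE]
    }
  }
  if (is(moving, "BinaryMask")) BinaryMask(out, voxelSpacing(reference))
  else VolumeGrid(out, voxelSpacing(reference))
}

#' Z-score normalisation over non-zero voxels
#'
#' Per-modality intensity standardisation: the mean and (population) standard
#' deviation are computed over non-zero voxels only, and the whole volume is
#' transformed by `(I - mu) / (sigma + eps)`. Zero-background voxels pass
#' through the same affine map by default, preserving a single linear
#' transform per modality; set `preserve_zero_background = TRUE` to pin them
#' to 0 instead. An all-zero volume is returned unchanged with a warning.
#'
#' @param grid a [VolumeGrid-class].
#' @param eps small positive stabiliser added to sigma (default 1e-8).
#' @param preserve_zero_background keep background voxels at exactly 0.
#' @return normalised [VolumeGrid-class].
#' @export
zscoreNormalize <- function(grid, eps = 1e-8, preserve_zero_background = FALSE) {
  x <- volData(grid)
  nz <- x != 0
  if (!any(nz)) {
    warning("all-zero volume: z-score normalisation skipped")
    return(grid)
  }
  v <- x[nz]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2)) # population (1/N) sd
  y <- (x - mu) / (sigma + eps)
  if (preserve_zero_background) y[!nz] <- 0
  VolumeGrid(y, voxelSpacing(grid))
}

#' Binarize a mask volume
#'
#' Voxels with intensity strictly greater than the threshold become lesion
#' (1); voxels less than or equal become background (0). Idempotent on
#' already-binary input at the default threshold 0.5.
#'
#' @param grid a [VolumeGrid-class] (or [BinaryMask-class]).
#' @param threshold scalar threshold, default 0.5.
#' @return a [BinaryMask-class].
#' @export
binarize <- function(grid, threshold = 0.5) {
  BinaryMask((volData(grid) > threshold) * 1, voxelSpacing(grid))
}

#' Patient-level cohort split
#'
#' Shuffles subject ids with a fixed seed and assigns them contiguously to
#' train/validation/test with floor-and-remainder rounding:
#' `train = floor(f1 * n)`, `val = floor(f2 * n)`, `test = remainder`. The
#' split is exhaustive and pairwise disjoint (no patient leakage) and
#' deterministic for a given seed.
#'
#' @param ids unique subject ids.
#' @param fractions length-3 fractions summing to 1 (default 0.70/0.15/0.15).
#' @param seed integer seed.
#' @return a `CohortSplit`: list with `train_ids`, `val_ids`, `test_ids`,
#'   `seed`.
#' @export
splitCohort <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 0L) {
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  n <- length(ids)
  if (n < 3L) stop("need at least 3 subjects to form a 3-way split")
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L)
    stop("fractions must be length 3 and sum to 1")
  perm <- withSeed(seed, sample(ids))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  structure(list(train_ids = perm[seq_len(n_train)],
                 val_ids = perm[n_train + seq_len(n_val)],
                 test_ids = perm[-seq_len(n_train + n_val)],
                 seed = as.integer(seed)),
            class = "CohortSplit")
}

#' Write a split manifest
#'
#' Plain-text audit table (subject_id, split) plus the seed as a header
#' comment.
#'
#' @param split a `CohortSplit` from [splitCohort()].
#' @param path output TSV path.
#' @export
writeSplitManifest <- function(split, path) {
  df <- data.frame(
    subject_id = c(split$train_ids, split$val_ids, split$test_ids),
    split = rep(c("train", "val", "test"),
                c(length(split$train_ids), length(split$val_ids),
                  length(split$test_ids))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed=", split$seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pooled lesion-ratio statistic
#'
#' The global lesion ratio of a cohort,
#' `100 * total lesion voxels / total voxels`, pooled over all masks — the
#' class-imbalance statistic that motivates lesion-aware patch sampling
#' (about 0.29% in typical MS cohorts).
#'
#' @param masks list of [BinaryMask-class].
#' @return a `CohortStats`: list with `total_lesion_voxels`, `total_voxels`,
#'   `lesion_ratio_percent`.
#' @export
lesionRatio <- function(masks) {
  if (!length(masks)) stop("empty mask list")
  lesion <- sum(vapply(masks, function(m) sum(volData(m)), numeric(1)))
  total <- sum(vapply(masks, function(m) prod(dim(volData(m))), numeric(1)))
  structure(list(total_lesion_voxels = lesion, total_voxels = total,
                 lesion_ratio_percent = 100 * lesion / total),
            class = "CohortStats")
}
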