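#' Single-modality volumetric grid
#'
#' A 3-D scalar field with its voxel spacing in millimetres, the unit of
#' single-modality image data throughout the package. Axes are canonicalised
#' to an anatomical order on load (closest-to-RAS), so array axes (D, H, W)
#' have a stable meaning across files.
#'
#' @slot data 3-D numeric array of voxel intensities; must be finite.
#' @slot spacing numeric length-3, strictly positive voxel edge lengths (mm).
#'
#' @seealso [readVolume()], [zscoreNormalize()], [resampleLike()]
#' @export
setClass("VolumeGrid",
         representation(data = "array", spacing = "numeric"),
         validity = function(object) {
           if (length(dim(object@data)) != 3L)
             return("data must be a 3-D array")
           if (any(dim(object@data) < 1L))
             return("all dimensions must be >= 1")
           if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
               any(object@spacing <= 0))
             return("spacing must be 3 strictly positive finite values")
           if (!all(is.finite(object@data)))
             return("data must be finite")
           TRUE
         })

#' Aligned multi-modal MRI volume
#'
#' A 4-D array holding the three MRI modalities channel-first in the fixed
#' order (T1, T2, FLAIR) on one shared voxel grid — the subject-level input
#' tensor of the segmentation networks.
#'
#' @slot channels 4-D numeric array of dim \code{c(3, D, H, W)}.
#' @slot spacing numeric length-3 voxel spacing (mm).
#'
#' @export
setClass("MultiModalVolume",
         representation(channels = "array", spacing = "numeric"),
         validity = function(object) {
           d <- dim(object@channels)
           if (length(d) != 4L || d[1] != 3L)
             return("channels must be a 4-D array with exactly 3 channels (T1, T2, FLAIR)")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             return("spacing must be 3 strictly positive values")
           TRUE
         })

#' Binary lesion mask
#'
#' A 3-D \{0,1\} label grid aligned to a [MultiModalVolume-class].
#'
#' @slot data 3-D numeric array containing only 0 and 1.
#' @slot spacing numeric length-3 voxel spacing (mm).
#'
#' @export
setClass("BinaryMask",
         representation(data = "array", spacing = "numeric"),
         validity = function(object) {
           if (length(dim(object@data)) != 3L)
             return("data must be a 3-D array")
           if (!all(object@data %in% c(0, 1)))
             return("mask values must be in {0, 1}")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             return("spacing must be 3 strictly positive values")
           TRUE
         })

#' Voxel-wise uncertainty map
#'
#' Pairs a mean lesion-probability field with a voxel-wise uncertainty field
#' (predictive entropy for MC dropout, population variance for deep
#' ensembles).
#'
#' @slot meanProb 3-D array of mean probabilities in [0, 1].
#' @slot uncertainty 3-D non-negative array (entropy in nats, bounded by
#'   ln 2; or variance, bounded by 0.25 for probabilities).
#' @slot method "mc_dropout" or "ensemble".
#' @slot nSamples number of stochastic passes or ensemble members.
#'
#' @export
setClass("UncertaintyMap",
         representation(meanProb = "array", uncertainty = "array",
                        method = "character", nSamples = "integer"),
         validity = function(object) {
           if (!identical(dim(object@meanProb), dim(object@uncertainty)))
             return("meanProb and uncertainty must share one shape")
           if (any(object@meanProb < 0 | object@meanProb > 1))
             return("meanProb must lie in [0, 1]")
           if (any(object@uncertainty < -1e-12))
             return("uncertainty must be non-negative")
           if (!object@method %in% c("mc_dropout", "ensemble"))
             return("method must be 'mc_dropout' or 'ensemble'")
           if (object@method == "mc_dropout" &&
               any(object@uncertainty > log(2) + 1e-9))
             return("entropy uncertainty cannot exceed ln 2")
           if (object@method == "ensemble" &&
               any(object@uncertainty > 0.25 + 1e-9))
             return("variance of probabilities cannot exceed 0.25")
           TRUE
         })

#' @describeIn VolumeGrid-class Construct a VolumeGrid.
#' @param data 3-D numeric array.
#' @param spacing voxel spacing (mm), default isotropic 1 mm.
#' @export
VolumeGrid <- function(data, spacing = c(1, 1, 1)) {
  new("VolumeGrid", data = data, spacing = as.numeric(spacing))
}

#' @describeIn MultiModalVolume-class Construct a MultiModalVolume.
#' @param channels 4-D array \code{c(3, D, H, W)} in (T1, T2, FLAIR) order.
#' @param spacing voxel spacing (mm).
#' @export
MultiModalVolume <- function(channels, spacing = c(1, 1, 1)) {
  new("MultiModalVolume", channels = channels, spacing = as.numeric(spacing))
}

#' @describeIn BinaryMask-class Construct a BinaryMask.
#' @param data 3-D array over \{0,1\}.
#' @param spacing voxel spacing (mm).
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1)) {
  storage.mode(data) <- "double"
  new("BinaryMask", data = data, spacing = as.numeric(spacing))
}

#' Accessors for volumetric containers
#'
#' @param x a [VolumeGrid-class], [MultiModalVolume-class], [BinaryMask-class]
#'   or [UncertaintyMap-class].
#' @return `volData()` the 3-D data array; `mmChannels()` the 4-D channel
#'   array; `voxelSpacing()` the length-3 spacing; `meanProb()` /
#'   `uncertaintyField()` the fields of an uncertainty map.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setMethod("volData", "VolumeGrid", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volData", "BinaryMask", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("mmChannels", function(x) standardGeneric("mmChannels"))
#' @rdname accessors
#' @export
setMethod("mmChannels", "MultiModalVolume", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MultiModalVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BinaryMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("meanProb", function(x) standardGeneric("meanProb"))
#' @rdname accessors
#' @export
setMethod("meanProb", "UncertaintyMap", function(x) x@meanProb)

#' @rdname accessors
#' @export
setGeneric("uncertaintyField", function(x) standardGeneric("uncertaintyField"))
#' @rdname accessors
#' @export
setMethod("uncertaintyField", "UncertaintyMap", function(x) x@uncertainty)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@data), max(object@data)))
})

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@channels)
  cat(sprintf("MultiModalVolume [T1,T2,FLAIR] %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm\n",
              d[2], d[3], d[4], object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  n <- sum(object@data)
  cat(sprintf("BinaryMask %dx%dx%d voxels, %d lesion voxels (%.4g%%)\n",
              d[1], d[2], d[3], as.integer(n), 100 * n / prod(d)))
})

setMethod("show", "UncertaintyMap", function(object) {
  d <- dim(object@meanProb)
  cat(sprintf("UncertaintyMap (%s, n=%d) %dx%dx%d voxels, mean uncertainty %.4g\n",
              object@method, object@nSamples, d[1], d[2], d[3],
              mean(object@uncertainty)))
})
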