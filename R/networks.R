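#' Specification of one MBConv3D block
#'
#' The mobile inverted-bottleneck block in 3-D: an optional 1x1x1 expansion
#' layer, a depthwise 3x3x3 convolution (stride 1 or 2; stride-2 depthwise
#' convolutions perform the spatial downsampling), and a linear 1x1x1
#' projection, with batch normalisation after each convolution and Swish
#' activations except after the projection. A residual connection is used
#' exactly when the block is stride 1 with equal input and output widths.
#'
#' @param in_channels,out_channels integer channel widths.
#' @param stride 1 or 2.
#' @param expansion_factor channel expansion of the inverted bottleneck
#'   (default 1, in which case the expansion layer is omitted).
#' @return an `MBConvSpec` list with the derived `use_residual` flag.
#' @export
mbconvSpec <- function(in_channels, out_channels, stride = 1L,
                       expansion_factor = 1L) {
  stopifnot(stride %in% c(1L, 2L), expansion_factor >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride),
                 expansion_factor = as.integer(expansion_factor),
                 use_residual = stride == 1L && in_channels == out_channels),
            class = "MBConvSpec")
}

#' Build an MBConv3D block
#'
#' Convolutions followed by batch norm carry no bias terms. Weight
#' initialisation consumes the current RNG stream.
#'
#' @param spec an [mbconvSpec()].
#' @return block object usable inside a network (environment with `$layers`).
#' @export
buildMBConv3d <- function(spec) {
  cin <- spec$in_channels
  cexp <- cin * spec$expansion_factor
  layers <- list()
  if (spec$expansion_factor > 1L) {
    layers <- c(layers, list(newConv3d(cin, cexp, k = 1L, pad = 0L),
                             newBatchNorm(cexp), newActivation("swish")))
  }
  layers <- c(layers, list(
    newConv3d(cexp, cexp, k = 3L, stride = spec$stride, pad = 1L, groups = cexp),
    newBatchNorm(cexp), newActivation("swish"),
    newConv3d(cexp, spec$out_channels, k = 1L, pad = 0L),
    newBatchNorm(spec$out_channels)))
  blk <- newLayer("mbconv")
  blk$spec <- spec
  blk$layers <- layers
  blk
}

mbconvForward <- function(blk, x, training = FALSE, mc = FALSE) {
  y <- seqForward(blk$layers, x, training, mc)
  if (blk$spec$use_residual) { blk$residual <- TRUE; y + x } else y
}

mbconvBackward <- function(blk, gy) {
  gx <- seqBackward(blk$layers, gy)
  if (blk$spec$use_residual) gx + gy else gx
}

doubleConv <- function(cin, cout) {
  list(newConv3d(cin, cout), newBatchNorm(cout), newActivation("relu"),
       newConv3d(cout, cout), newBatchNorm(cout), newActivation("relu"))
}

#' Declarative network specification
#'
#' Describes either segmentation architecture; networks and parameter counts
#' derive from it.
#'
#' For `"efficientnet3d_unet"` (the proposed network): a 3x3x3 stem
#' convolution to `stem_channels` with batch norm and Swish; four stride-2
#' MBConv3D encoder stages at `encoder_channels`; a stride-1 MBConv3D
#' bottleneck to `bottleneck_channels`; four decoder stages, each trilinear
#' 2x upsampling, a 1x1x1 convolution onto the stage width, concatenation
#' with the matching encoder skip and an MBConv3D block to the stage width;
#' finally a 1x1x1 convolution (the only biased convolution) with sigmoid.
#'
#' For `"unet3d_baseline"`: a 3x3x3 stem convolution (BN + ReLU), four
#' encoder levels of DoubleConv3D + 2x2x2 max pooling at `encoder_channels`,
#' a DoubleConv3D bottleneck, and four decoder levels of 2x2x2 transposed
#' convolution + skip concatenation + DoubleConv3D at `decoder_channels`;
#' `bottleneck_channels = 256` reproduces the narrower bottleneck reading of
#' the baseline description.
#'
#' Spatial (channel-wise) dropout at `dropout_rate` follows each decoder
#' block; it is active during training and, on request, during Monte-Carlo
#' dropout inference.
#'
#' @param variant `"efficientnet3d_unet"` or `"unet3d_baseline"`.
#' @param stem_channels,encoder_channels,bottleneck_channels,decoder_channels
#'   channel ladder (defaults per variant; encoder/decoder must have 4
#'   stages).
#' @param dropout_rate decoder dropout rate in [0, 1); defaults 0.25
#'   (proposed) / 0.2 (baseline).
#' @param expansion_factor MBConv expansion (proposed variant; default 1).
#' @param in_channels,out_channels input modalities (3) and output maps (1).
#' @return a `NetworkSpec` list.
#' @export
networkSpec <- function(variant = c("efficientnet3d_unet", "unet3d_baseline"),
                        stem_channels = NULL, encoder_channels = NULL,
                        bottleneck_channels = NULL, decoder_channels = NULL,
                        dropout_rate = NULL, expansion_factor = 1L,
                        in_channels = 3L, out_channels = 1L) {
  variant <- match.arg(variant)
  if (variant == "efficientnet3d_unet") {
    stem_channels <- stem_channels %||% 32L
    encoder_channels <- encoder_channels %||% c(32L, 48L, 64L, 96L)
    bottleneck_channels <- bottleneck_channels %||% 256L
    decoder_channels <- decoder_channels %||% c(160L, 96L, 64L, 48L)
    dropout_rate <- dropout_rate %||% 0.25
  } else {
    stem_channels <- stem_channels %||% 32L
    encoder_channels <- encoder_channels %||% c(64L, 128L, 256L, 512L)
    bottleneck_channels <- bottleneck_channels %||% 512L
    decoder_channels <- decoder_channels %||% c(256L, 128L, 64L, 32L)
    dropout_rate <- dropout_rate %||% 0.2
  }
  stopifnot(length(encoder_channels) == 4L, length(decoder_channels) == 4L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(variant = variant,
                 stem_channels = as.integer(stem_channels),
                 encoder_channels = as.integer(encoder_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 decoder_channels = as.integer(decoder_channels),
                 dropout_rate = dropout_rate,
                 expansion_factor = as.integer(expansion_factor),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "NetworkSpec")
}

#' Build a segmentation network from its specification
#'
#' Weight initialisation (He-normal) is deterministic given `seed`.
#'
#' @param spec a [networkSpec()].
#' @param seed integer initialisation seed.
#' @return a network object (environment) accepted by [predictPatch()],
#'   [slidingWindowPredict()], [trainModel()] and
#'   [countTrainableParameters()].
#' @export
buildNetwork <- function(spec, seed = 0L) {
  withSeed(seed, {
    net <- newLayer("network")
    net$spec <- spec
    net$variant <- spec$variant
    if (spec$variant == "efficientnet3d_unet") {
      enc_ch <- spec$encoder_channels
      dec_ch <- spec$decoder_channels
      net$stem <- list(newConv3d(spec$in_channels, spec$stem_channels),
                       newBatchNorm(spec$stem_channels), newActivation("swish"))
      ins <- c(spec$stem_channels, enc_ch[-4])
      net$enc <- lapply(seq_len(4), function(i)
        buildMBConv3d(mbconvSpec(ins[i], enc_ch[i], stride = 2L,
                                 expansion_factor = spec$expansion_factor)))
      net$bottleneck <- buildMBConv3d(
        mbconvSpec(enc_ch[4], spec$bottleneck_channels,
                   expansion_factor = spec$expansion_factor))
      # decoder stage j: upsample, 1x1x1 conv onto dec_ch[j], concat skip,
      # MBConv to dec_ch[j], spatial dropout
      skips <- c(enc_ch[3], enc_ch[2], enc_ch[1], spec$stem_channels)
      prev <- spec$bottleneck_channels
      net$dec <- lapply(seq_len(4), function(j) {
        st <- list(
          up = newUpsample2(),
          pre = list(newConv3d(prev, dec_ch[j], k = 1L, pad = 0L),
                     newBatchNorm(dec_ch[j]), newActivation("swish")),
          mb = buildMBConv3d(mbconvSpec(dec_ch[j] + skips[j], dec_ch[j],
                                        expansion_factor = spec$expansion_factor)),
          drop = newDropout3d(spec$dropout_rate),
          skip_ch = skips[j], cat_c1 = dec_ch[j])
        prev <<- dec_ch[j]
        st
      })
      net$head <- list(newConv3d(dec_ch[4], spec$out_channels, k = 1L,
                                 pad = 0L, bias = TRUE),
                       newActivation("sigmoid"))
    } else {
      enc_ch <- spec$encoder_channels
      dec_ch <- spec$decoder_channels
      net$stem <- list(newConv3d(spec$in_channels, spec$stem_channels),
                       newBatchNorm(spec$stem_channels), newActivation("relu"))
      ins <- c(spec$stem_channels, enc_ch[-4])
      net$enc <- lapply(seq_len(4), function(i) {
        blk <- newLayer("unet_enc")
        blk$conv <- doubleConv(ins[i], enc_ch[i])
        blk$pool <- newMaxPool2()
        blk
      })
      net$bottleneck_layers <- doubleConv(enc_ch[4], spec$bottleneck_channels)
      skips <- c(enc_ch[4], enc_ch[3], enc_ch[2], enc_ch[1])
      prev <- spec$bottleneck_channels
      net$dec <- lapply(seq_len(4), function(j) {
        st <- list(up = newUpConv2(prev, dec_ch[j]),
                   conv = doubleConv(dec_ch[j] + skips[j], dec_ch[j]),
                   drop = newDropout3d(spec$dropout_rate),
                   skip_ch = skips[j], cat_c1 = dec_ch[j])
        prev <<- dec_ch[j]
        st
      })
      net$head <- list(newConv3d(dec_ch[4], spec$out_channels, k = 1L,
                                 pad = 0L, bias = TRUE),
                       newActivation("sigmoid"))
    }
    net
  })
}

# All primitive layers of a network, in forward order.
netLayers <- function(net) {
  out <- list()
  add <- function(x) {
    if (is.environment(x) && !is.null(x$layers)) out[c(length(out) + seq_along(x$layers))] <<- x$layers
    else if (is.environment(x)) out[[length(out) + 1]] <<- x
    else for (e in x) add(e)
  }
  add(net$stem)
  for (blk in net$enc) {
    if (identical(blk$type, "unet_enc")) { add(blk$conv); add(blk$pool) }
    else add(blk)
  }
  if (!is.null(net$bottleneck)) add(net$bottleneck) else add(net$bottleneck_layers)
  for (st in net$dec) {
    add(st$up)
    if (!is.null(st$pre)) add(st$pre)
    if (!is.null(st$mb)) add(st$mb) else add(st$conv)
    add(st$drop)
  }
  add(net$head)
  out
}

#' Forward pass of a built network
#'
#' @param net network from [buildNetwork()].
#' @param x input array `[in_channels, D, H, W]`; spatial dims must be
#'   divisible by 16 (four stride-2 stages).
#' @param training enable batch-statistics and dropout (training mode).
#' @param mc keep dropout active while using running batch statistics
#'   (Monte-Carlo dropout inference).
#' @return probability array `[out_channels, D, H, W]`.
#' @export
netForward <- function(net, x, training = FALSE, mc = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[1] != net$spec$in_channels)
    stop("input must be [", net$spec$in_channels, ", D, H, W]")
  if (any(d[-1] %% 16L != 0L))
    stop("spatial dimensions must be divisible by 16 (four stride-2 stages); got ",
         paste(d[-1], collapse = "x"))
  if (net$variant == "efficientnet3d_unet") {
    s0 <- seqForward(net$stem, x, training, mc)
    skips <- vector("list", 4)
    h <- s0
    for (i in 1:4) {
      skips[[i]] <- h # resolution entering stage i
      h <- mbconvForward(net$enc[[i]], h, training, mc)
    }
    h <- mbconvForward(net$bottleneck, h, training, mc)
    # decoder uses skips at matching resolution: enc3 out, enc2 out, enc1 out, stem
    dec_skips <- list(skips[[4]], skips[[3]], skips[[2]], skips[[1]])
    for (j in 1:4) {
      st <- net$dec[[j]]
      h <- layerForward(st$up, h, training, mc)
      h <- seqForward(st$pre, h, training, mc)
      h <- catChannels(h, dec_skips[[j]])
      h <- mbconvForward(st$mb, h, training, mc)
      h <- layerForward(st$drop, h, training, mc)
    }
    net$dec_skips_dims <- lapply(dec_skips, dim)
    seqForward(net$head, h, training, mc)
  } else {
    h <- seqForward(net$stem, x, training, mc)
    skips <- vector("list", 4)
    for (i in 1:4) {
      blk <- net$enc[[i]]
      h <- seqForward(blk$conv, h, training, mc)
      skips[[i]] <- h
      h <- layerForward(blk$pool, h, training, mc)
    }
    h <- seqForward(net$bottleneck_layers, h, training, mc)
    dec_skips <- list(skips[[4]], skips[[3]], skips[[2]], skips[[1]])
    for (j in 1:4) {
      st <- net$dec[[j]]
      h <- layerForward(st$up, h, training, mc)
      h <- catChannels(h, dec_skips[[j]])
      h <- seqForward(st$conv, h, training, mc)
      h <- layerForward(st$drop, h, training, mc)
    }
    seqForward(net$head, h, training, mc)
  }
}

# Backward pass; accumulates parameter gradients in the layers and returns
# the gradient at the input. Must follow a training-mode forward pass.
netBackward <- function(net, gy) {
  g <- seqBackward(net$head, gy)
  if (net$variant == "efficientnet3d_unet") {
    gskips <- vector("list", 4)
    for (j in 4:1) {
      st <- net$dec[[j]]
      g <- layerBackward(st$drop, g)
      g <- mbconvBackward(st$mb, g)
      sp <- splitChannels(g, st$cat_c1)
      gskips[[j]] <- sp[[2]]
      g <- seqBackward(st$pre, sp[[1]])
      g <- layerBackward(st$up, g)
    }
    g <- mbconvBackward(net$bottleneck, g)
    # dec stage j consumed skip entering enc stage (5 - j)
    for (i in 4:1) {
      g <- mbconvBackward(net$enc[[i]], g)
      g <- g + gskips[[5 - i]]
    }
    seqBackward(net$stem, g)
  } else {
    gskips <- vector("list", 4)
    for (j in 4:1) {
      st <- net$dec[[j]]
      g <- layerBackward(st$drop, g)
      g <- seqBackward(st$conv, g)
      sp <- splitChannels(g, st$cat_c1)
      gskips[[j]] <- sp[[2]]
      g <- layerBackward(st$up, sp[[1]])
    }
    g <- seqBackward(net$bottleneck_layers, g)
    for (i in 4:1) {
      blk <- net$enc[[i]]
      g <- layerBackward(blk$pool, g)
      g <- g + gskips[[5 - i]]
      g <- seqBackward(blk$conv, g)
    }
    seqBackward(net$stem, g)
  }
}

#' Count trainable parameters
#'
#' Sum of all trainable tensor sizes (convolution weights, the head bias,
#' and batch-norm scale/shift; running statistics are not trainable).
#'
#' @param net network from [buildNetwork()] (or a single block environment).
#' @return integer parameter count.
#' @export
countTrainableParameters <- function(net) {
  layers <- if (identical(net$type, "network")) netLayers(net)
            else if (!is.null(net$layers)) net$layers
            else list(net)
  sum(vapply(layers, function(l)
    sum(vapply(l$param_names, function(nm) length(l[[nm]]), numeric(1)), 0),
    numeric(1)))
}

#' Predict lesion probabilities for one patch
#'
#' Eval-mode forward pass (dropout off, running batch statistics) unless
#' `mc = TRUE` requests Monte-Carlo dropout.
#'
#' @param net network from [buildNetwork()].
#' @param patch_image array `[3, s, s, s]`, spatial dims divisible by 16.
#' @param mc keep dropout active (MC-dropout sampling).
#' @return probability array `[s, s, s]`, values strictly inside (0, 1).
#' @export
predictPatch <- function(net, patch_image, mc = FALSE) {
  y <- netForward(net, patch_image, training = FALSE, mc = mc)
  out <- array(y, dim(y)[-1])
  clearCaches(netLayers(net))
  out
}

#' Sliding-window whole-volume prediction
#'
#' Tiles the volume with windows of side `patch_size` at the given fractional
#' overlap, averages overlapping window probabilities with uniform weights
#' (per-voxel weights sum to one by construction), and zero-pads volumes
#' smaller than one window before cropping back.
#'
#' @param net network from [buildNetwork()].
#' @param volume a [MultiModalVolume-class] (z-score normalised channels).
#' @param patch_size window side (divisible by 16).
#' @param overlap fractional window overlap in [0, 1).
#' @param mc Monte-Carlo dropout mode for each window pass.
#' @param return_weights also return the accumulated per-voxel weight map
#'   (diagnostic).
#' @return a [VolumeGrid-class] of voxel-wise lesion probabilities (list
#'   with `probs` and `weights` when `return_weights`).
#' @export
slidingWindowPredict <- function(net, volume, patch_size = 64L, overlap = 0.5,
                                 mc = FALSE, return_weights = FALSE) {
  if (patch_size %% 16L != 0L) stop("patch_size must be divisible by 16")
  ch <- mmChannels(volume)
  shape <- dim(ch)[-1]
  padded <- pmax(shape, patch_size)
  if (any(padded != shape)) {
    tmp <- array(0, c(3L, padded))
    tmp[, seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3])] <- ch
    ch <- tmp
  }
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap))))
  starts <- lapply(seq_len(3), function(a) {
    s <- seq(0L, padded[a] - patch_size, by = stride)
    sort(unique(c(s, padded[a] - patch_size)))
  })
  acc <- array(0, padded)
  wts <- array(0, padded)
  for (sd_ in starts[[1]]) for (sh in starts[[2]]) for (sw in starts[[3]]) {
    idx <- list(sd_ + seq_len(patch_size), sh + seq_len(patch_size),
                sw + seq_len(patch_size))
    win <- ch[, idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    p <- predictPatch(net, win, mc = mc)
    acc[idx[[1]], idx[[2]], idx[[3]]] <- acc[idx[[1]], idx[[2]], idx[[3]]] + p
    wts[idx[[1]], idx[[2]], idx[[3]]] <- wts[idx[[1]], idx[[2]], idx[[3]]] + 1
  }
  probs <- acc / wts
  probs <- probs[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
  dim(probs) <- shape
  out <- VolumeGrid(probs, voxelSpacing(volume))
  if (return_weights) {
    w <- wts / wts
    list(probs = out, weights = w[seq_len(shape[1]), seq_len(shape[2]),
                                  seq_len(shape[3]), drop = FALSE])
  } else out
}
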