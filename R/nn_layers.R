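# Minimal 3-D conv-net engine: layers are environments holding parameters,
# gradients and forward caches; layerForward()/layerBackward() dispatch on
# $type. Arrays are [C, D, H, W] with the channel axis fastest, so per-channel
# parameters broadcast by plain vector recycling. Single-threaded and
# double-precision throughout for bit-reproducible training.

sigmoidFn <- function(x) 1 / (1 + exp(-x))

newLayer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

# He-normal initialisation; consumes the current RNG stream.
newConv3d <- function(cin, cout, k = 3L, stride = 1L, pad = NULL,
                      groups = 1L, bias = FALSE) {
  pad <- pad %||% (k %/% 2L)
  fan_in <- (cin / groups) * k^3
  w <- array(rnorm(cout * (cin / groups) * k^3, sd = sqrt(2 / fan_in)),
             c(cout, cin / groups, k, k, k))
  l <- newLayer("conv3d", cin = as.integer(cin), cout = as.integer(cout),
                k = as.integer(k), stride = as.integer(stride),
                pad = as.integer(pad), groups = as.integer(groups),
                w = w, gw = NULL, b = NULL, gb = NULL)
  l$param_names <- "w"
  if (bias) {
    l$b <- numeric(cout)
    l$param_names <- c("w", "b")
  }
  l
}

newBatchNorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  l <- newLayer("bn", ch = as.integer(ch), eps = eps, momentum = momentum,
                gamma = rep(1, ch), beta = numeric(ch),
                ggamma = NULL, gbeta = NULL,
                running_mean = numeric(ch), running_var = rep(1, ch))
  l$param_names <- c("gamma", "beta")
  l
}

newActivation <- function(kind) newLayer(kind)

newDropout3d <- function(p) newLayer("dropout3d", p = p)

newMaxPool2 <- function() newLayer("maxpool2")

newUpsample2 <- function() newLayer("upsample2")

newUpConv2 <- function(cin, cout) {
  w <- array(rnorm(cout * cin * 8, sd = sqrt(2 / (cin * 8))),
             c(cout, cin, 2L, 2L, 2L))
  l <- newLayer("upconv2", cin = as.integer(cin), cout = as.integer(cout),
                w = w, gw = NULL)
  l$param_names <- "w"
  l
}

layerForward <- function(l, x, training = FALSE, mc = FALSE) {
  switch(l$type,
    conv3d = {
      l$x <- x
      y <- cpp_conv3d(x, dim(x), l$w, l$k, l$stride, l$pad, l$groups)
      if (!is.null(l$b)) y <- y + l$b # channel axis fastest: plain recycling
      l$ydim <- dim(y)
      y
    },
    upconv2 = {
      l$x <- x
      y <- cpp_upconv2(x, dim(x), l$w, l$cout)
      l$ydim <- dim(y)
      y
    },
    bn = {
      # Normalisation statistics come from the current sample's spatial
      # voxels in every mode (batches are formed by gradient accumulation,
      # so the sample is the batch). Using the same statistics at inference
      # keeps train/eval consistent and avoids the amplification of
      # near-zero-variance channels by stale running estimates; running
      # statistics are still tracked for diagnostics.
      C <- l$ch
      N <- length(x) / C
      xm <- matrix(x, nrow = C)
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu^2
      v[v < 0] <- 0
      if (training) {
        l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
        l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- (x - mu) * invstd
      if (training) { l$xhat <- xhat; l$invstd <- invstd; l$N <- N }
      xhat * l$gamma + l$beta
    },
    swish = {
      s <- sigmoidFn(x)
      l$x <- x; l$s <- s
      x * s
    },
    relu = {
      l$pos <- x > 0
      x * l$pos
    },
    sigmoid = {
      y <- sigmoidFn(x)
      l$y <- y
      y
    },
    dropout3d = {
      if ((training || mc) && l$p > 0) {
        C <- dim(x)[1]
        keep <- (runif(C) >= l$p) / (1 - l$p)
        l$keep <- keep
        x * keep
      } else {
        l$keep <- NULL
        x
      }
    },
    maxpool2 = {
      l$xdim <- dim(x)
      r <- cpp_maxpool2(x, dim(x))
      l$argmax <- r$argmax
      r$y
    },
    upsample2 = {
      l$xdim <- dim(x)
      cpp_upsample2(x, dim(x))
    },
    stop("unknown layer type: ", l$type))
}

layerBackward <- function(l, gy) {
  switch(l$type,
    conv3d = {
      gw <- cpp_conv3d_grad_weight(l$x, dim(l$x), gy, l$ydim, l$k, l$stride,
                                   l$pad, l$groups)
      l$gw <- if (is.null(l$gw)) gw else l$gw + gw
      if (!is.null(l$b)) {
        gb <- rowSums(matrix(gy, nrow = l$cout))
        l$gb <- if (is.null(l$gb)) gb else l$gb + gb
      }
      cpp_conv3d_grad_input(gy, l$ydim, l$w, dim(l$x), l$k, l$stride, l$pad,
                            l$groups)
    },
    upconv2 = {
      gw <- cpp_upconv2_grad_weight(l$x, dim(l$x), gy, l$ydim)
      l$gw <- if (is.null(l$gw)) gw else l$gw + gw
      cpp_upconv2_grad_input(gy, l$ydim, l$w, dim(l$x))
    },
    bn = {
      C <- l$ch
      gym <- matrix(gy, nrow = C)
      xhm <- matrix(l$xhat, nrow = C)
      sg <- rowSums(gym)
      sgx <- rowSums(gym * xhm)
      ggamma <- sgx
      gbeta <- sg
      l$ggamma <- if (is.null(l$ggamma)) ggamma else l$ggamma + ggamma
      l$gbeta <- if (is.null(l$gbeta)) gbeta else l$gbeta + gbeta
      gx <- (l$gamma * l$invstd / l$N) * (l$N * gy - sg - l$xhat * sgx)
      dim(gx) <- dim(gy)
      gx
    },
    swish = {
      gy * (l$s * (1 + l$x * (1 - l$s)))
    },
    relu = gy * l$pos,
    sigmoid = gy * l$y * (1 - l$y),
    dropout3d = if (is.null(l$keep)) gy else gy * l$keep,
    maxpool2 = cpp_maxpool2_grad(gy, l$argmax, l$xdim),
    upsample2 = cpp_upsample2_grad(gy, l$xdim),
    stop("unknown layer type: ", l$type))
}

seqForward <- function(layers, x, training = FALSE, mc = FALSE) {
  for (l in layers) x <- layerForward(l, x, training, mc)
  x
}

seqBackward <- function(layers, gy) {
  for (l in rev(layers)) gy <- layerBackward(l, gy)
  gy
}

# Drop forward caches after an optimisation step to bound memory.
clearCaches <- function(layers) {
  for (l in layers) {
    for (nm in c("x", "xhat", "invstd", "s", "pos", "y", "keep", "argmax"))
      if (exists(nm, envir = l, inherits = FALSE)) rm(list = nm, envir = l)
  }
  invisible(NULL)
}
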