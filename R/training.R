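#' Cosine-annealed learning rate
#'
#' `lr_min + (lr0 - lr_min) * (1 + cos(pi * (epoch %% t_max) / t_max)) / 2`,
#' the smooth within-cycle decay from `lr0` (epoch 0) to `lr_min` (epoch
#' `t_max`), restarting each cycle.
#'
#' @param epoch 0-based epoch index.
#' @param lr0 initial learning rate.
#' @param t_max cycle length in epochs.
#' @param lr_min floor learning rate (default 0).
#' @return learning rate for `epoch`.
#' @export
cosineAnnealingLR <- function(epoch, lr0, t_max, lr_min = 0) {
  if (t_max <= 0) stop("t_max must be positive")
  stopifnot(epoch >= 0)
  e <- epoch %% t_max
  lr_min + (lr0 - lr_min) * (1 + cos(pi * e / t_max)) / 2
}

#' Training configuration
#'
#' Defaults follow the reproducibility table of the study protocol: Adam
#' with model-specific initial learning rates (1e-4 baseline, 5e-4 proposed
#' network), cosine-annealing cycle of 80 epochs, batches of 4 patches, at
#' most 120 epochs with early-stopping patience 25, composite loss weight
#' alpha = 0.7, no weight decay. The `"text_343"` preset instead uses the
#' alternative narrative values (3e-5 / 1e-4, cycle 10); the active preset
#' is recorded in the returned object and logged by [trainModel()].
#'
#' @param variant network variant the config drives.
#' @param preset `"table3"` (default) or `"text_343"`.
#' @param lr0 initial learning rate; default per variant and preset.
#' @param t_max cosine cycle length in epochs.
#' @param batch_size patches per optimiser step (gradient accumulation).
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs.
#' @param patches_per_epoch training patches drawn per epoch.
#' @param alpha composite-loss Dice weight.
#' @param val_patch_size window side for validation sliding-window
#'   prediction.
#' @param seed integer seed controlling sampling order.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(variant = c("efficientnet3d_unet", "unet3d_baseline"),
                        preset = c("table3", "text_343"),
                        lr0 = NULL, t_max = NULL, batch_size = 4L,
                        max_epochs = 120L, patience = 25L,
                        patches_per_epoch = 100L, alpha = 0.7,
                        val_patch_size = 64L, seed = 0L) {
  variant <- match.arg(variant)
  preset <- match.arg(preset)
  defaults <- list(
    table3 = list(efficientnet3d_unet = 5e-4, unet3d_baseline = 1e-4, t_max = 80L),
    text_343 = list(efficientnet3d_unet = 1e-4, unet3d_baseline = 3e-5, t_max = 10L))
  lr0 <- lr0 %||% defaults[[preset]][[variant]]
  t_max <- t_max %||% defaults[[preset]]$t_max
  stopifnot(lr0 > 0, patience >= 1, batch_size >= 1, max_epochs >= 1,
            patches_per_epoch >= 1)
  structure(list(variant = variant, preset = preset, lr0 = lr0,
                 t_max = as.integer(t_max), batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 patches_per_epoch = as.integer(patches_per_epoch),
                 alpha = alpha, val_patch_size = as.integer(val_patch_size),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# ---- Adam ----

adamInit <- function(layers) {
  states <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in l$param_names) {
      key <- paste0(i, ".", nm)
      states[[key]] <- list(m = 0 * l[[nm]], v = 0 * l[[nm]])
    }
  }
  list(states = states, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamStep <- function(opt, layers, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in l$param_names) {
      g <- l[[switch(nm, w = "gw", b = "gb", gamma = "ggamma", beta = "gbeta")]]
      if (is.null(g)) next
      key <- paste0(i, ".", nm)
      st <- opt$states[[key]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      opt$states[[key]] <- st
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      l[[nm]] <- l[[nm]] - upd
    }
  }
  opt
}

zeroGrads <- function(layers) {
  for (l in layers)
    for (nm in c("gw", "gb", "ggamma", "gbeta"))
      if (!is.null(l[[nm]])) l[[nm]] <- NULL
  invisible(NULL)
}

# ---- checkpoint state ----

#' Extract / restore network weights
#'
#' `stateDict()` deep-copies every trainable tensor and batch-norm running
#' statistic; `loadStateDict()` writes such a copy back into a network built
#' from the same spec.
#'
#' @param net network from [buildNetwork()].
#' @param state list produced by `stateDict()`.
#' @return `stateDict()`: named list of arrays; `loadStateDict()`: the
#'   network, invisibly.
#' @export
stateDict <- function(net) {
  layers <- netLayers(net)
  st <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in c(l$param_names,
                 if (identical(l$type, "bn")) c("running_mean", "running_var")))
      st[[paste0(i, ".", nm)]] <- l[[nm]]
  }
  st
}

#' @rdname stateDict
#' @param state a state list from `stateDict()`.
#' @export
loadStateDict <- function(net, state) {
  layers <- netLayers(net)
  for (key in names(state)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    nm <- parts[2]
    layers[[i]][[nm]] <- state[[key]]
  }
  invisible(net)
}

# Pooled validation Dice over whole volumes via sliding-window prediction,
# thresholded at 0.5.
validationDice <- function(net, val_subjects, patch_size, overlap = 0.5) {
  tp <- 0; fp <- 0; fn <- 0
  for (s in val_subjects) {
    pv <- slidingWindowPredict(net, s$volume, patch_size, overlap)
    pred <- volData(pv) > 0.5
    truth <- volData(s$mask) == 1
    tp <- tp + sum(pred & truth)
    fp <- fp + sum(pred & !truth)
    fn <- fn + sum(!pred & truth)
  }
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' Train a segmentation network
#'
#' Adam updates with the composite Dice + BCE loss over patches drawn from
#' `train_stream` (gradient accumulation forms batches of
#' `config$batch_size`), a cosine-annealed learning rate, per-epoch
#' validation by whole-volume sliding-window prediction and pooled Dice on
#' `val_subjects`, early stopping after `config$patience` epochs without
#' validation improvement, and checkpointing of the best-validation-Dice
#' epoch (the returned weights are the best epoch's, not the last). A
#' non-finite loss aborts with a diagnostic.
#'
#' @param net network from [buildNetwork()].
#' @param train_stream function() -> `Patch`, e.g. [balancedPatchStream()].
#' @param val_subjects list of subjects (each with `volume`, `mask`) for
#'   validation; may be empty if `val_evaluator` is supplied.
#' @param config a [trainConfig()].
#' @param val_evaluator optional function(net, epoch) -> validation Dice,
#'   replacing the sliding-window evaluation (used for schedule tests and
#'   custom protocols).
#' @param verbose print one line per epoch.
#' @return list with `checkpoint` (spec, best state, config) and `history`
#'   (`TrainHistory` data.frame: epoch, train_loss, val_dice, lr; plus
#'   `best_epoch`, `stopped_early`).
#' @export
trainModel <- function(net, train_stream, val_subjects, config,
                       val_evaluator = NULL, verbose = FALSE) {
  layers <- netLayers(net)
  opt <- adamInit(layers)
  loss_cfg <- lossConfig(alpha = config$alpha)
  steps <- max(1L, config$patches_per_epoch %/% config$batch_size)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_dice = numeric(0), lr = numeric(0))
  best_dice <- -Inf
  best_epoch <- 0L
  best_state <- NULL
  stopped_early <- FALSE
  if (verbose)
    message(sprintf("training %s (preset %s, lr0=%g, t_max=%d)",
                    config$variant, config$preset, config$lr0, config$t_max))
  train_rng <- rngStream(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- cosineAnnealingLR(epoch - 1L, config$lr0, config$t_max)
    epoch_loss <- 0
    n_pat <- 0L
    for (step in seq_len(steps)) {
      zeroGrads(layers)
      for (b in seq_len(config$batch_size)) {
        p <- train_stream()
        y <- train_rng(netForward(net, p$image, training = TRUE))
        target <- array(p$mask, dim(y))
        loss <- compositeLoss(as.numeric(y), as.numeric(target), loss_cfg)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch, ", step ", step)
        epoch_loss <- epoch_loss + loss
        n_pat <- n_pat + 1L
        gy <- compositeLossGrad(y, target, loss_cfg)
        # head ends in a sigmoid layer; push the probability-space gradient
        netBackward(net, gy / config$batch_size)
      }
      opt <- adamStep(opt, layers, lr)
      clearCaches(layers)
    }
    val_dice <- if (!is.null(val_evaluator)) val_evaluator(net, epoch)
                else validationDice(net, val_subjects, config$val_patch_size)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_pat,
                                         val_dice = val_dice, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  lr %.2e",
                      epoch, epoch_loss / n_pat, val_dice, lr))
    if (val_dice > best_dice) {
      best_dice <- val_dice
      best_epoch <- epoch
      best_state <- stateDict(net)
    } else if (epoch - best_epoch >= config$patience) {
      stopped_early <- TRUE
      break
    }
  }
  if (!is.null(best_state)) loadStateDict(net, best_state)
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stopped_early") <- stopped_early
  list(checkpoint = list(spec = net$spec, state = best_state,
                         config = config, best_epoch = best_epoch,
                         best_val_dice = best_dice),
       history = history, net = net)
}

#' Train a deep ensemble
#'
#' Trains `n_members` replicas that differ only by seed (weight
#' initialisation and patch-sampling order); all members share one
#' configuration. Duplicate seeds are an error.
#'
#' @param n_members number of members (>= 2; the study protocol uses 5).
#' @param spec a [networkSpec()].
#' @param stream_factory function(seed) -> patch stream for one member.
#' @param val_subjects validation subjects passed to [trainModel()].
#' @param config a [trainConfig()]; each member gets `seed = seeds[k]`.
#' @param seeds integer member seeds (default `config$seed + 0:(n-1)`).
#' @param verbose forwarded to [trainModel()].
#' @return list of checkpoints (one per member, each with its history).
#' @export
trainEnsemble <- function(n_members = 5L, spec, stream_factory, val_subjects,
                          config, seeds = NULL, verbose = FALSE) {
  stopifnot(n_members >= 2L)
  seeds <- seeds %||% (config$seed + seq_len(n_members) - 1L)
  if (anyDuplicated(seeds)) stop("ensemble member seeds must be distinct")
  if (length(seeds) != n_members) stop("need one seed per member")
  lapply(seq_len(n_members), function(k) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    net <- buildNetwork(spec, seed = seeds[k])
    fit <- trainModel(net, stream_factory(seeds[k]), val_subjects, cfg,
                      verbose = verbose)
    c(fit$checkpoint, list(history = fit$history, seed = seeds[k]))
  })
}
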