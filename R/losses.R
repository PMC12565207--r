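#' Composite loss configuration
#'
#' @param alpha weight of the Dice term in the composite loss (default 0.7);
#'   the binary cross-entropy term gets `1 - alpha`.
#' @param eps smoothing constant of the soft Dice loss (default 1e-6), which
#'   keeps the loss finite when predicted and true masks are nearly empty.
#' @return a `LossConfig` list.
#' @export
lossConfig <- function(alpha = 0.7, eps = 1e-6) {
  stopifnot(alpha >= 0, alpha <= 1, eps > 0)
  structure(list(alpha = alpha, eps = eps), class = "LossConfig")
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*y) + eps) / (sum(p^2) + sum(y^2) + eps)` — the
#' squared-denominator soft form of the Dice similarity coefficient, used as
#' an overlap-based training objective. Bounded in [0, 1]; equals 0 for a
#' perfect binary match and for the empty-empty case (smoothing).
#'
#' @param pred probability field in [0, 1].
#' @param target \{0,1\} field of the same shape.
#' @param eps smoothing constant.
#' @return scalar loss.
#' @export
diceLoss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  1 - (2 * sum(pred * target) + eps) / (sum(pred^2) + sum(target^2) + eps)
}

#' Binary cross-entropy loss
#'
#' Negative mean log-likelihood
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`, with probabilities clipped to
#' `[delta, 1 - delta]` before the logarithms so saturated sigmoids cannot
#' produce infinities. Non-negative, minimised at perfect prediction.
#'
#' @param pred probability field in [0, 1].
#' @param target \{0,1\} field of the same shape.
#' @param delta clipping constant (default 1e-7).
#' @return scalar loss.
#' @export
bceLoss <- function(pred, target, delta = 1e-7) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  p <- pmin(pmax(pred, delta), 1 - delta)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Composite Dice + BCE loss
#'
#' `alpha * Dice + (1 - alpha) * BCE`, the convex combination of the
#' overlap-based and voxel-wise penalties used to train both networks.
#'
#' @param pred probability field in [0, 1].
#' @param target \{0,1\} field.
#' @param config a `LossConfig`.
#' @return scalar loss.
#' @export
compositeLoss <- function(pred, target, config = lossConfig()) {
  config$alpha * diceLoss(pred, target, config$eps) +
    (1 - config$alpha) * bceLoss(pred, target)
}

# Gradient of the composite loss w.r.t. the predicted probabilities.
# Used by the training loop; kept analytic so training needs one backward
# pass only.
compositeLossGrad <- function(pred, target, config = lossConfig(),
                              delta = 1e-7) {
  num <- 2 * sum(pred * target) + config$eps
  den <- sum(pred^2) + sum(target^2) + config$eps
  g_dice <- -(2 * target * den - num * 2 * pred) / den^2
  p <- pmin(pmax(pred, delta), 1 - delta)
  g_bce <- (-target / p + (1 - target) / (1 - p)) / length(pred)
  g <- config$alpha * g_dice + (1 - config$alpha) * g_bce
  dim(g) <- dim(pred)
  g
}

#' Voxel-level confusion counts
#'
#' @param pred_binary \{0,1\} predicted field.
#' @param target \{0,1\} reference field of the same shape.
#' @return a `ConfusionCounts` list with `TP`, `FP`, `TN`, `FN` (their sum is
#'   the number of voxels evaluated).
#' @export
confusionCounts <- function(pred_binary, target) {
  if (!identical(dim(pred_binary) %||% length(pred_binary),
                 dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  if (!all(pred_binary %in% c(0, 1)) || !all(target %in% c(0, 1)))
    stop("confusionCounts requires binary inputs")
  tp <- sum(pred_binary == 1 & target == 1)
  fp <- sum(pred_binary == 1 & target == 0)
  fn <- sum(pred_binary == 0 & target == 1)
  tn <- sum(pred_binary == 0 & target == 0)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
            class = "ConfusionCounts")
}

#' Segmentation metric report
#'
#' Computes Dice `2TP/(2TP+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, accuracy `(TP+TN)/total` and specificity `TN/(TN+FP)` from
#' confusion counts. Ratios of the form 0/0 are reported as 0 with the
#' metric named in the `undefined` field, which keeps cohort aggregation
#' total instead of raising.
#'
#' @param counts a `ConfusionCounts`, or a \{0,1\} predicted field (then
#'   `target` must be given).
#' @param target optional \{0,1\} reference field.
#' @return a `MetricReport` list: `dice`, `precision`, `recall`, `accuracy`,
#'   `specificity`, `undefined`.
#' @export
metricReport <- function(counts, target = NULL) {
  if (!inherits(counts, "ConfusionCounts"))
    counts <- confusionCounts(counts, target)
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  with(counts, {
    rep <- list(
      dice = safe(2 * TP, 2 * TP + FP + FN, "dice"),
      precision = safe(TP, TP + FP, "precision"),
      recall = safe(TP, TP + FN, "recall"),
      accuracy = safe(TP + TN, TP + FP + TN + FN, "accuracy"),
      specificity = safe(TN, TN + FP, "specificity"))
    rep$undefined <- undef
    structure(rep, class = "MetricReport")
  })
}

#' Cohort metric table
#'
#' Flat per-subject metric table with an added pooled row. `pooled` sums the
#' confusion counts over subjects before computing metrics (the default
#' cohort summary); the alternative is the unweighted mean of per-subject
#' metrics, reported in the `macro` row.
#'
#' @param preds list of \{0,1\} predicted fields (or [BinaryMask-class]).
#' @param targets list of matching references.
#' @param ids optional subject ids.
#' @return data.frame subject_id x metric with `pooled` and `macro` rows.
#' @export
cohortMetricTable <- function(preds, targets, ids = NULL) {
  stopifnot(length(preds) == length(targets), length(preds) >= 1)
  getArr <- function(x) if (is(x, "BinaryMask")) volData(x) else x
  ids <- ids %||% sprintf("sub-%03d", seq_along(preds))
  rows <- list()
  pool <- list(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in seq_along(preds)) {
    cc <- confusionCounts(getArr(preds[[i]]), getArr(targets[[i]]))
    for (k in names(pool)) pool[[k]] <- pool[[k]] + cc[[k]]
    r <- metricReport(cc)
    rows[[i]] <- data.frame(subject_id = ids[i], dice = r$dice,
                            precision = r$precision, recall = r$recall,
                            accuracy = r$accuracy, specificity = r$specificity)
  }
  df <- do.call(rbind, rows)
  pr <- metricReport(structure(pool, class = "ConfusionCounts"))
  df <- rbind(df, data.frame(subject_id = "pooled", dice = pr$dice,
                             precision = pr$precision, recall = pr$recall,
                             accuracy = pr$accuracy,
                             specificity = pr$specificity))
  macro <- colMeans(df[seq_along(preds), -1, drop = FALSE])
  rbind(df, data.frame(subject_id = "macro", t(macro)))
}
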