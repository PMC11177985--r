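# Training losses (binary cross-entropy, soft Dice, soft IoU) and
# evaluation metrics (confusion counts, IoU/Jaccard, DSC/F1, accuracy,
# precision, recall) for per-pixel infarct segmentation.

.check_pair <- function(p, y) {
  if (!all(dim(p) == dim(y) | (is.null(dim(p)) && is.null(dim(y)))))
    stop("prediction and ground truth shapes differ")
  if (length(p) != length(y))
    stop("prediction and ground truth shapes differ")
  if (!all(y %in% c(0, 1))) stop("ground truth mask must be binary")
  if (any(!is.finite(p))) stop("predicted map contains non-finite values")
  invisible(NULL)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over all pixels, with predictions
#' clipped to `[eps, 1-eps]` to guard the logarithm.
#'
#' @param p predicted values in \[0, 1\] (any array shape)
#' @param y binary ground-truth mask, same shape
#' @param eps clipping constant (default 1e-7)
#' @return scalar loss, >= 0
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  .check_pair(p, y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

# gradient of bce_loss w.r.t. p (clipped region passes zero slope through
# the clip, matching the subgradient of the clipped objective)
bce_loss_grad <- function(p, y, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  g <- (-y / pc + (1 - y) / (1 - pc)) / length(p)
  dim(g) <- dim(p)
  g
}

#' Soft Dice loss
#'
#' Squared-denominator soft Dice complement
#' `1 - (2 sum(p y) + s) / (sum(p^2) + sum(y^2) + s)` with smoothing
#' constant `s` so empty masks are defined. Computed per sample (4th array
#' dimension, if present) and averaged.
#'
#' @inheritParams bce_loss
#' @param smooth smoothing constant (default 1e-6)
#' @return scalar loss in \[0, 1\]
#' @export
dsc_loss <- function(p, y, smooth = 1e-6) {
  .check_pair(p, y)
  f <- function(pp, yy)
    1 - (2 * sum(pp * yy) + smooth) / (sum(pp^2) + sum(yy^2) + smooth)
  .per_sample_mean(p, y, f)
}

dsc_loss_grad <- function(p, y, smooth = 1e-6) {
  .per_sample_grad(p, y, function(pp, yy) {
    num <- 2 * sum(pp * yy) + smooth
    den <- sum(pp^2) + sum(yy^2) + smooth
    -(2 * yy * den - num * 2 * pp) / den^2
  })
}

#' Soft IoU (Jaccard) loss
#'
#' `1 - (sum(p y) + s) / (sum(p + y - p y) + s)`, computed per sample and
#' averaged.
#'
#' @inheritParams dsc_loss
#' @return scalar loss in \[0, 1\]
#' @export
iou_loss <- function(p, y, smooth = 1e-6) {
  .check_pair(p, y)
  f <- function(pp, yy)
    1 - (sum(pp * yy) + smooth) / (sum(pp + yy - pp * yy) + smooth)
  .per_sample_mean(p, y, f)
}

iou_loss_grad <- function(p, y, smooth = 1e-6) {
  .per_sample_grad(p, y, function(pp, yy) {
    num <- sum(pp * yy) + smooth
    den <- sum(pp + yy - pp * yy) + smooth
    -(yy * den - num * (1 - yy)) / den^2
  })
}

#' Mean squared error loss
#' @inheritParams bce_loss
#' @return scalar loss, >= 0
#' @export
mse_loss <- function(p, y) {
  .check_pair(p, y)
  mean((p - y)^2)
}

mse_loss_grad <- function(p, y) {
  g <- 2 * (p - y) / length(p)
  dim(g) <- dim(p)
  g
}

.per_sample_mean <- function(p, y, f) {
  d <- dim(p)
  if (is.null(d) || length(d) < 4) return(f(p, y))
  N <- d[4]
  mean(vapply(seq_len(N), function(n)
    f(p[, , , n], y[, , , n]), numeric(1)))
}

.per_sample_grad <- function(p, y, gf) {
  d <- dim(p)
  if (is.null(d) || length(d) < 4) {
    g <- gf(p, y)
    dim(g) <- d
    return(g)
  }
  N <- d[4]
  g <- array(0, d)
  for (n in seq_len(N)) g[, , , n] <- gf(p[, , , n], y[, , , n]) / N
  g
}

#' Loss function registry
#'
#' @param name `"bce"`, `"dsc"`, `"iou"`, or `"mse"`
#' @return list with `loss(p, y)` and `grad(p, y)` functions
#' @export
get_loss <- function(name = c("bce", "dsc", "iou", "mse")) {
  name <- match.arg(name)
  switch(name,
         bce = list(name = "bce", loss = bce_loss, grad = bce_loss_grad),
         dsc = list(name = "dsc", loss = dsc_loss, grad = dsc_loss_grad),
         iou = list(name = "iou", loss = iou_loss, grad = iou_loss_grad),
         mse = list(name = "mse", loss = mse_loss, grad = mse_loss_grad))
}

#' Confusion counts between a predicted and a ground-truth mask
#'
#' TP are correctly predicted infarct pixels, FP incorrectly predicted
#' infarct pixels, FN infarct pixels missed by the model, TN the rest.
#'
#' @param pred binary predicted mask
#' @param y binary ground-truth mask, same shape
#' @return object of class `confusion_counts`: list(TP, FP, FN, TN)
#' @export
confusion <- function(pred, y) {
  if (length(pred) != length(y)) stop("mask shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("confusion requires binary masks")
  TP <- sum(pred == 1 & y == 1)
  FP <- sum(pred == 1 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  TN <- sum(pred == 0 & y == 0)
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN),
            class = "confusion_counts")
}

#' Jaccard index (IoU) from confusion counts
#'
#' `TP / (TP + FP + FN)`; when both masks are empty the score is defined
#' as 1.
#'
#' @param counts `confusion_counts`
#' @return scalar in \[0, 1\]
#' @export
iou_score <- function(counts) {
  den <- counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  counts$TP / den
}

#' Dice similarity coefficient (F1) from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; empty-vs-empty masks score 1.
#'
#' @inheritParams iou_score
#' @return scalar in \[0, 1\]
#' @export
dsc_score <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  2 * counts$TP / den
}

#' Segmentation metric report
#'
#' Accuracy, precision, recall, IoU and DSC from a predicted and a
#' ground-truth binary mask (or their confusion counts).
#'
#' @param pred binary predicted mask (or `confusion_counts`)
#' @param y binary ground-truth mask (ignored if `pred` is counts)
#' @return named list of the five metrics
#' @export
segmentation_metrics <- function(pred, y = NULL) {
  counts <- if (inherits(pred, "confusion_counts")) pred else confusion(pred, y)
  N <- counts$TP + counts$FP + counts$FN + counts$TN
  list(accuracy = (counts$TP + counts$TN) / N,
       precision = if (counts$TP + counts$FP == 0) 1
                   else counts$TP / (counts$TP + counts$FP),
       recall = if (counts$TP + counts$FN == 0) 1
                else counts$TP / (counts$TP + counts$FN),
       iou = iou_score(counts),
       dsc = dsc_score(counts))
}

#' Per-example metric table and summary for a set of predictions
#'
#' @param preds list of binary predicted masks
#' @param ys list of binary ground-truth masks
#' @param csv optional path for the per-example CSV report
#' @param json optional path for the JSON summary (mean and sd per metric)
#' @return data frame, one row per example
#' @export
metric_report <- function(preds, ys, csv = NULL, json = NULL) {
  stopifnot(length(preds) == length(ys))
  rows <- lapply(seq_along(preds), function(i)
    as.data.frame(segmentation_metrics(preds[[i]], ys[[i]])))
  df <- do.call(rbind, rows)
  df <- cbind(example = seq_along(preds), df)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json)) {
    summ <- lapply(df[-1], function(v) list(mean = mean(v), sd = stats::sd(v)))
    writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA), json)
  }
  df
}
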