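# Gradient-based training of segmentation networks: Adam optimizer,
# minibatching, early stopping on validation loss with best-weight restore.

.adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# one forward/backward pass over a batch; returns loss and gradient list
.train_step <- function(model, xb, yb, lossfn, training = TRUE) {
  tp <- ag_tape()
  pn <- lapply(model$params, ag_param)
  xn <- ag_const(xb)
  out <- .forward_network(tp, pn, model, xn, training = training)
  lv <- lossfn$loss(out$val, yb)
  g <- lossfn$grad(out$val, yb)
  ag_backward(tp, out, g)
  grads <- lapply(pn, function(nd) nd$grad)
  list(loss = lv, grads = grads)
}

.batch_loss <- function(model, images, lossfn, batch = 8L) {
  b <- images_to_batch(images)
  N <- dim(b$x)[4]
  tot <- 0
  for (s in seq(1, N, by = batch)) {
    e <- min(s + batch - 1, N)
    p <- predict_probs(model, b$x[, , , s:e, drop = FALSE])
    tot <- tot + lossfn$loss(p, b$y[, , , s:e, drop = FALSE]) * (e - s + 1)
  }
  tot / N
}

.snapshot <- function(model)
  list(params = model$params, bn = lapply(model$bn, as.list))

.restore <- function(model, snap) {
  model$params <- snap$params
  for (nm in names(snap$bn)) {
    model$bn[[nm]]$running_mean <- snap$bn[[nm]]$running_mean
    model$bn[[nm]]$running_var <- snap$bn[[nm]]$running_var
  }
  model
}

#' Train a segmentation network
#'
#' Minimizes the chosen loss with Adam over minibatches. Validation loss is
#' monitored each epoch; training stops early after `patience` epochs
#' without improvement and the best weights are restored.
#'
#' @param model `segmentation_model`
#' @param train,val lists of `bullseye_image`
#' @param loss `"bce"`, `"dsc"`, `"iou"`, or `"mse"`
#' @param epochs maximum epochs
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param patience early-stopping patience (epochs)
#' @param seed seed for batch shuffling
#' @param verbose print per-epoch losses
#' @return the trained model, with a `history` attribute: data frame of
#'   per-epoch train/validation loss
#' @export
train_model <- function(model, train, val = NULL, loss = "bce",
                        epochs = 10L, batch_size = 8L, lr = 1e-3,
                        patience = 5L, seed = 1L, verbose = FALSE) {
  if (length(train) == 0) stop("empty training split")
  lossfn <- get_loss(loss)
  tb <- images_to_batch(train)
  N <- dim(tb$x)[4]
  set.seed(as.integer(seed))
  opt <- .adam_init(model$params)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(loss = Inf, snap = .snapshot(model), epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (s in seq(1, N, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, N)]
      st <- .train_step(model,
                        tb$x[, , , idx, drop = FALSE],
                        tb$y[, , , idx, drop = FALSE], lossfn)
      upd <- .adam_step(model$params, st$grads, opt, lr = lr)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + st$loss * length(idx)
    }
    ep_loss <- ep_loss / N
    vl <- if (is.null(val) || length(val) == 0) ep_loss
          else .batch_loss(model, val, lossfn)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss, vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, snap = .snapshot(model), epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model <- .restore(model, best$snap)
  attr(model, "history") <- hist
  attr(model, "best_epoch") <- best$epoch
  model
}

#' Evaluate a model on a set of bullseye images
#'
#' @param model `segmentation_model` or `multifidelity_model`
#' @param images list of `bullseye_image`
#' @param threshold binarization threshold
#' @return list with `metrics` (pooled over all pixels), `per_example`
#'   data frame, and `mean_dsc`
#' @export
evaluate_model <- function(model, images, threshold = 0.5) {
  stopifnot(length(images) >= 1)
  b <- images_to_batch(images)
  pred <- predict_mask(model, b$x, threshold)
  pooled <- segmentation_metrics(as.vector(pred), as.vector(b$y))
  N <- dim(b$x)[4]
  per <- metric_report(
    lapply(seq_len(N), function(i) pred[, , , i]),
    lapply(seq_len(N), function(i) b$y[, , , i]))
  list(metrics = pooled, per_example = per, mean_dsc = mean(per$dsc))
}
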