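# Composite multi-fidelity network: a low-fidelity UNet (NN_LF) plus a
# linear (NN_HF1) and a nonlinear (NN_HF2) high-fidelity correction, each a
# single 10x10 convolution over the channel stack of the high-fidelity
# image x_H (3 channels) and the low-fidelity prediction y_L = NN_LF(x_H)
# (1 channel). The combined output is y_H = F_l + F_nl, trained jointly
# with MSE_L + MSE_H + lambda * sum(beta^2).

# asymmetric padding that preserves spatial size for an even 10x10 kernel
.PAD10 <- c(4L, 5L, 4L, 5L)

#' Build the composite multi-fidelity model
#'
#' @param config `network_config` for the low-fidelity UNet
#' @param lambda L2 regularization rate on all kernel weights of both
#'   fidelity branches (default 1e-4)
#' @param leaky_slope negative slope of the nonlinear branch's leaky ReLU
#' @param seed seed for the high-fidelity kernel initialization (the UNet
#'   uses `config$seed`)
#' @return object of class `multifidelity_model` with fields `nn_lf`,
#'   `hf_params` (`hf1.w`, `hf1.b`, `hf2.w`, `hf2.b`), `lambda`,
#'   `leaky_slope`
#' @export
build_multifidelity <- function(config = network_config("unet"),
                                lambda = 1e-4, leaky_slope = 0.01,
                                seed = NULL) {
  stopifnot(inherits(config, "network_config"), lambda >= 0)
  nn_lf <- build_network(config)
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(as.integer(seed))
  lim <- sqrt(6 / (10 * 10 * 4))
  hf <- list(
    hf1.w = array(stats::runif(10 * 10 * 4, -lim, lim), c(10, 10, 4, 1)),
    hf1.b = 0,
    hf2.w = array(stats::runif(10 * 10 * 4, -lim, lim), c(10, 10, 4, 1)),
    hf2.b = 0)
  structure(list(nn_lf = nn_lf, hf_params = hf, lambda = lambda,
                 leaky_slope = leaky_slope),
            class = "multifidelity_model")
}

#' @export
print.multifidelity_model <- function(x, ...) {
  cat(sprintf(
    "multi-fidelity composite: %s + 2 x 10x10 CNN kernels (%s parameters)\n",
    x$nn_lf$config$architecture,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# forward through both high-fidelity branches; pn_hf holds the four HF
# parameter nodes, y_l_node the LF prediction node (shared tape)
.forward_hf <- function(tp, pn_hf, x_node, y_l_node, leaky_slope) {
  stack <- ag_concat_c(tp, x_node, y_l_node)
  f_l <- ag_conv2d(tp, stack, pn_hf$hf1.w, pn_hf$hf1.b, 1L, .PAD10)
  f_nl <- ag_leaky_relu(tp, ag_conv2d(tp, stack, pn_hf$hf2.w, pn_hf$hf2.b,
                                      1L, .PAD10), leaky_slope)
  ag_add(tp, f_l, f_nl)
}

#' Multi-fidelity forward pass
#'
#' `y_H = F_l(x_H, y_L) + F_nl(x_H, y_L)` with `y_L = NN_LF(x_H)`. The raw
#' sum is unbounded; it is clipped to \[0, 1\] so it can be thresholded
#' into a binary mask.
#'
#' @param model `multifidelity_model`
#' @param x input `[H, W, 3, N]` batch (or single image / `bullseye_image`)
#' @param clip clip the output into \[0, 1\] (default TRUE)
#' @return array `[H, W, 1, N]`
#' @export
predict_multifidelity <- function(model, x, clip = TRUE) {
  x <- .as_batch(x)
  tp <- ag_tape()
  pn <- lapply(model$nn_lf$params, ag_const)
  pn_hf <- lapply(model$hf_params, ag_const)
  xn <- ag_const(x)
  y_l <- .forward_network(tp, pn, model$nn_lf, xn, training = FALSE)
  y_h <- .forward_hf(tp, pn_hf, xn, y_l, model$leaky_slope)
  out <- y_h$val
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Multi-fidelity loss terms
#'
#' `total = MSE_L + MSE_H + lambda * sum(beta_i^2)` where `MSE_L` is the
#' mean squared error of the low-fidelity predictions against the
#' low-fidelity masks, `MSE_H` the same over the high-fidelity samples
#' (per-pixel means, so the two terms are scale-comparable), and the
#' regularizer runs over the kernel weights of both fidelity branches.
#'
#' @param p_l,y_l low-fidelity predictions and masks (`[H, W, 1, N_L]`)
#' @param p_h,y_h high-fidelity predictions and masks (`[H, W, 1, N_H]`)
#' @param weights list of weight arrays entering the regularizer
#' @param lambda L2 regularization rate, >= 0
#' @return object of class `multifidelity_loss_terms`:
#'   list(mse_l, mse_h, reg, total)
#' @export
multifidelity_loss <- function(p_l, y_l, p_h, y_h, weights = list(),
                               lambda = 0) {
  stopifnot(lambda >= 0)
  if (length(p_l) == 0 || length(p_h) == 0)
    stop("empty low- or high-fidelity batch")
  mse_l <- mean((p_l - y_l)^2)
  mse_h <- mean((p_h - y_h)^2)
  reg <- lambda * sum(vapply(weights, function(w) sum(w^2), numeric(1)))
  structure(list(mse_l = mse_l, mse_h = mse_h, reg = reg,
                 total = mse_l + mse_h + reg),
            class = "multifidelity_loss_terms")
}

# kernel weights (no biases) of both branches, for the regularizer
.mf_reg_weights <- function(model) {
  wl <- model$nn_lf$params[grepl("\\.w$", names(model$nn_lf$params))]
  c(wl, model$hf_params[c("hf1.w", "hf2.w")])
}

#' Train the composite multi-fidelity network
#'
#' Joint end-to-end minimization of `MSE_L + MSE_H + lambda sum(beta^2)` by
#' Adam: each step combines a low-fidelity minibatch (through the UNet
#' alone) with the full high-fidelity training set (through the composite),
#' accumulating gradients for `theta`, `gamma1`, `gamma2` on one tape. The
#' high-fidelity training set is one example plus its three fixed rotations
#' (N_H = 4); the held-out high-fidelity example is never seen.
#'
#' @param model `multifidelity_model`
#' @param lf_images list of low-fidelity `bullseye_image` (N_LFR samples)
#' @param hf_train one high-fidelity `bullseye_image`; augmented internally
#' @param hf_eval optional held-out high-fidelity image; supplying the same
#'   example as `hf_train` is a data-leakage error
#' @param epochs,batch_size,lr,seed training protocol
#' @param verbose print per-epoch losses
#' @return trained `multifidelity_model` with a `history` attribute
#' @export
train_multifidelity <- function(model, lf_images, hf_train, hf_eval = NULL,
                                epochs = 10L, batch_size = 8L, lr = 1e-3,
                                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "multifidelity_model"))
  if (length(lf_images) == 0)
    stop("N_LFR = 0: at least one low-fidelity sample is required")
  if (!is.null(hf_eval) &&
      identical(hf_train$meta$source_id, hf_eval$meta$source_id) &&
      identical(hf_train$pixels, hf_eval$pixels))
    stop("data leakage: high-fidelity train and eval examples are identical")
  hf_set <- augment_rotations(hf_train)
  hb <- images_to_batch(hf_set)
  lb <- images_to_batch(lf_images)
  N_L <- dim(lb$x)[4]
  set.seed(as.integer(seed))
  all_params <- c(model$nn_lf$params, model$hf_params)
  opt <- .adam_init(all_params)
  lam <- model$lambda
  hist <- data.frame(epoch = integer(0), mse_l = numeric(0),
                     mse_h = numeric(0), reg = numeric(0),
                     total = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N_L)
    ep_terms <- c(mse_l = 0, mse_h = 0, reg = 0, total = 0)
    nb <- 0L
    for (s in seq(1, N_L, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, N_L)]
      tp <- ag_tape()
      pn <- lapply(model$nn_lf$params, ag_param)
      pn_hf <- lapply(model$hf_params, ag_param)
      # low-fidelity branch
      xl <- ag_const(lb$x[, , , idx, drop = FALSE])
      p_l <- .forward_network(tp, pn, model$nn_lf, xl, training = TRUE)
      # high-fidelity composite
      xh <- ag_const(hb$x)
      y_l_h <- .forward_network(tp, pn, model$nn_lf, xh, training = TRUE)
      p_h <- .forward_hf(tp, pn_hf, xh, y_l_h, model$leaky_slope)
      terms <- multifidelity_loss(p_l$val, lb$y[, , , idx, drop = FALSE],
                                  p_h$val, hb$y,
                                  weights = .mf_reg_weights(model),
                                  lambda = lam)
      ag_backward(tp, p_h, mse_loss_grad(p_h$val, hb$y))
      ag_backward(tp, p_l, mse_loss_grad(p_l$val,
                                         lb$y[, , , idx, drop = FALSE]))
      grads <- c(lapply(pn, function(nd) nd$grad),
                 lapply(pn_hf, function(nd) nd$grad))
      if (lam > 0) {
        for (k in names(grads)) {
          if (grepl("\\.w$", k) && !is.null(grads[[k]]))
            grads[[k]] <- grads[[k]] + 2 * lam * all_params[[k]]
        }
      }
      upd <- .adam_step(all_params, grads, opt, lr = lr)
      all_params <- upd$params
      opt <- upd$state
      model$nn_lf$params <- all_params[names(model$nn_lf$params)]
      model$hf_params <- all_params[names(model$hf_params)]
      ep_terms <- ep_terms + unlist(terms)
      nb <- nb + 1L
    }
    ep_terms <- ep_terms / nb
    hist <- rbind(hist, data.frame(epoch = ep, t(ep_terms)))
    if (verbose)
      message(sprintf("epoch %3d  MSE_L %.5f  MSE_H %.5f  total %.5f",
                      ep, ep_terms["mse_l"], ep_terms["mse_h"],
                      ep_terms["total"]))
  }
  attr(model, "history") <- hist
  model
}

#' Ablation over the number of low-fidelity training samples
#'
#' For each requested low-fidelity count and seed, trains the multi-fidelity
#' composite and the single-fidelity UNet baseline (low-fidelity data only)
#' and records the held-out high-fidelity DSC of each.
#'
#' @param lf_images list of low-fidelity `bullseye_image` (the library)
#' @param hf_pair list of two high-fidelity `bullseye_image`; the first is
#'   the training example, the second held out (swap the list to reverse
#'   roles)
#' @param counts integer vector of low-fidelity sample counts, e.g.
#'   `c(20, 200, 400, 592)`
#' @param n_seeds number of random seed initializations (>= 2)
#' @param config `network_config` for both models
#' @param epochs,batch_size,lr training protocol
#' @param lambda multi-fidelity regularization rate
#' @return list with `runs` (data frame: n_lf, seed, model, dsc) and
#'   `summary` (mean and sd DSC per count and model)
#' @export
ablate_lf_count <- function(lf_images, hf_pair, counts = c(20, 200, 400, 592),
                            n_seeds = 5L, config = network_config("unet"),
                            epochs = 10L, batch_size = 8L, lr = 1e-3,
                            lambda = 1e-4) {
  stopifnot(length(counts) >= 1, n_seeds >= 2, length(hf_pair) == 2)
  if (max(counts) > length(lf_images))
    stop("requested count ", max(counts), " exceeds library size ",
         length(lf_images))
  rows <- list()
  for (cnt in counts) {
    for (sd2 in seq_len(n_seeds)) {
      set.seed(sd2 * 131L + cnt)
      sub <- lf_images[sample.int(length(lf_images), cnt)]
      cfg <- config
      cfg$seed <- config$seed + sd2
      mf <- build_multifidelity(cfg, lambda = lambda)
      mf <- train_multifidelity(mf, sub, hf_pair[[1]], hf_pair[[2]],
                                epochs = epochs, batch_size = batch_size,
                                lr = lr, seed = cfg$seed)
      dsc_mf <- evaluate_model(mf, hf_pair[2])$mean_dsc
      sf <- build_network(cfg)
      sf <- train_model(sf, sub, loss = "mse", epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        patience = epochs, seed = cfg$seed)
      dsc_sf <- evaluate_model(sf, hf_pair[2])$mean_dsc
      rows[[length(rows) + 1L]] <- data.frame(
        n_lf = cnt, seed = sd2,
        model = c("multi_fidelity", "single_fidelity"),
        dsc = c(dsc_mf, dsc_sf))
    }
  }
  runs <- do.call(rbind, rows)
  summ <- stats::aggregate(dsc ~ n_lf + model, runs,
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
  summ <- cbind(summ[c("n_lf", "model")], as.data.frame(summ$dsc))
  list(runs = runs, summary = summ)
}
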