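# Desk-scale reproduction of the experiment grid: image-size comparison,
# loss-function comparison, architecture comparison, and the multi-fidelity
# low-fidelity-count ablation, with seeded, re-runnable configurations.

#' Experiment configuration
#'
#' Full defaults match the training protocol (100 epochs, early-stopping
#' patience 5, batch size 128, image size 128, Adam). `scaled = TRUE`
#' switches to desk-scale settings (small library, few epochs, small batch,
#' reduced network width) so a full comparison grid runs on one CPU in
#' minutes.
#'
#' @param name experiment label
#' @param epochs maximum training epochs
#' @param patience early-stopping patience
#' @param batch_size minibatch size
#' @param image_size square input side length
#' @param base_channels first-level network width
#' @param lr Adam learning rate
#' @param n_examples library size before augmentation
#' @param fractions train/val/test split fractions
#' @param seeds integer vector of seeds
#' @param scaled use desk-scale defaults
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(name = "experiment", epochs = 100L,
                              patience = 5L, batch_size = 128L,
                              image_size = 128L, base_channels = 16L,
                              lr = 1e-3, n_examples = 592L,
                              fractions = c(0.7, 0.15, 0.15),
                              seeds = 1L, scaled = FALSE) {
  if (scaled) {
    if (missing(epochs)) epochs <- 12L
    if (missing(batch_size)) batch_size <- 8L
    if (missing(base_channels)) base_channels <- 4L
    if (missing(n_examples)) n_examples <- 24L
  }
  structure(list(name = name, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels), lr = lr,
                 n_examples = as.integer(n_examples), fractions = fractions,
                 seeds = as.integer(seeds), scaled = scaled),
            class = "experiment_config")
}

#' Build an augmented, split dataset for experiments
#'
#' Generates the synthetic library, renders bullseye images at the
#' configured size, applies fixed-rotation augmentation and the grouped
#' split.
#'
#' @param config `experiment_config`
#' @param domain generator domain
#' @param image_size optional override of `config$image_size`
#' @return `dataset_split`
#' @export
experiment_dataset <- function(config, domain = "low_fidelity",
                               image_size = NULL) {
  gc2 <- generator_config(n_examples = config$n_examples,
                          seed = config$seeds[1])
  lib <- build_library(gc2, domain = domain)
  size <- if (is.null(image_size)) config$image_size else image_size
  imgs <- preprocess_library(lib, size = size)
  imgs <- augment_rotations(imgs)
  split_dataset(imgs, config$fractions, seed = config$seeds[1])
}

#' Train one model under an experiment configuration
#'
#' Runs seeded training with early stopping on validation loss, then
#' reports accuracy, precision, recall, IoU and DSC on the test split.
#'
#' @param config `experiment_config`
#' @param data `dataset_split`
#' @param architecture one of the four architectures
#' @param loss `"bce"`, `"dsc"`, `"iou"`, or `"mse"`
#' @return list with `model`, `history`, `metrics`, `log`
#' @export
run_training <- function(config, data, architecture = "unet", loss = "bce") {
  stopifnot(inherits(config, "experiment_config"),
            inherits(data, "dataset_split"))
  if (length(data$train) == 0) stop("empty training split")
  if (length(data$test) == 0) stop("empty test split")
  size <- dim(data$train[[1]]$pixels)[1]
  ncfg <- network_config(architecture, input_size = size,
                         base_channels = config$base_channels,
                         seed = config$seeds[1])
  model <- build_network(ncfg)
  model <- train_model(model, data$train, data$val, loss = loss,
                       epochs = config$epochs,
                       batch_size = config$batch_size, lr = config$lr,
                       patience = config$patience, seed = config$seeds[1])
  ev <- evaluate_model(model, data$test)
  hist <- attr(model, "history")
  log <- list(
    config_hash = .hash_config(config),
    seed = config$seeds[1],
    architecture = architecture, loss = loss,
    image_size = size,
    n_train = length(data$train), n_val = length(data$val),
    n_test = length(data$test),
    best_epoch = attr(model, "best_epoch"),
    epoch_losses = hist)
  list(model = model, history = hist, metrics = ev$metrics,
       per_example = ev$per_example, log = log)
}

.hash_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  # small deterministic text hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%x", h)
}

.metric_row <- function(label_name, label_value, res) {
  cbind(stats::setNames(data.frame(label_value, stringsAsFactors = FALSE),
                        label_name),
        as.data.frame(res$metrics))
}

#' Compare image sizes
#'
#' Trains the UNet with BCE loss at each image size and reports one metric
#' row per size.
#'
#' @param config `experiment_config`
#' @param sizes image sizes (default 128, 256, 512)
#' @return data frame, one row per size
#' @export
compare_image_sizes <- function(config, sizes = c(128L, 256L, 512L)) {
  rows <- lapply(sizes, function(sz) {
    data <- experiment_dataset(config, image_size = sz)
    res <- run_training(config, data, architecture = "unet", loss = "bce")
    .metric_row("image_size", sz, res)
  })
  do.call(rbind, rows)
}

#' Compare loss functions
#'
#' Trains the UNet at a fixed image size (128) under BCE, DSC and IoU
#' losses.
#'
#' @param config `experiment_config`
#' @param data optional pre-built `dataset_split` (built at size 128 if
#'   omitted)
#' @param losses loss names
#' @return data frame, one row per loss
#' @export
compare_losses <- function(config, data = NULL,
                           losses = c("bce", "dsc", "iou")) {
  if (is.null(data)) data <- experiment_dataset(config, image_size = 128L)
  rows <- lapply(losses, function(ls) {
    res <- run_training(config, data, architecture = "unet", loss = ls)
    .metric_row("loss", ls, res)
  })
  do.call(rbind, rows)
}

#' Compare the four architectures
#'
#' Common data and loss; each row reports the five metrics plus the
#' trainable parameter count.
#'
#' @param config `experiment_config`
#' @param data optional pre-built `dataset_split`
#' @param loss common training loss
#' @return data frame, one row per architecture
#' @export
compare_architectures <- function(config, data = NULL, loss = "bce") {
  if (is.null(data)) data <- experiment_dataset(config)
  rows <- lapply(ARCHITECTURES, function(arch) {
    res <- run_training(config, data, architecture = arch, loss = loss)
    row <- .metric_row("architecture", arch, res)
    row$parameters <- count_parameters(res$model)
    row
  })
  do.call(rbind, rows)
}
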