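# Encoder-decoder segmentation networks: UNet, attention UNet, dense UNet,
# residual attention UNet. Five encoder levels with channel widths doubling
# from `base_channels` (16, 32, 64, 128, 256 at the default), two 3x3
# convolutions per level with ReLU, 2x2 max pooling between levels; decoder
# of 2x2 transposed convolutions, skip concatenation and two 3x3
# convolutions per level; final 1x1 convolution + sigmoid. The base UNet
# carries no batch normalization; dense blocks (dense UNet) use
# conv -> BN -> ReLU.

ARCHITECTURES <- c("unet", "attention_unet", "dense_unet",
                   "residual_attention_unet")

#' Network configuration
#'
#' @param architecture one of `"unet"`, `"attention_unet"`, `"dense_unet"`,
#'   `"residual_attention_unet"`
#' @param input_size square input side length; must be divisible by 16
#'   (five resolution levels)
#' @param in_channels input channels (3: CRL bullseye image)
#' @param base_channels first-level width; widths double per level
#' @param depth number of encoder levels (fixed at 5)
#' @param seed seed for weight initialization
#' @return object of class `network_config`
#' @export
network_config <- function(architecture = "unet", input_size = 128L,
                           in_channels = 3L, base_channels = 16L,
                           depth = 5L, seed = 1L) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  if (depth != 5L) stop("depth is fixed at 5")
  if (input_size %% 16L != 0L)
    stop("input_size must be divisible by 16, got ", input_size)
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = 5L, seed = as.integer(seed)),
            class = "network_config")
}

.widths <- function(config) config$base_channels * 2L^(0:4)

# ---- parameter specification tables ---------------------------------------

.spec_conv <- function(name, kh, kw, cin, cout)
  list(name = name, type = "conv", kh = kh, kw = kw, cin = cin, cout = cout)
.spec_convt <- function(name, cin, cout)
  list(name = name, type = "convt", kh = 2, kw = 2, cin = cin, cout = cout)
.spec_bn <- function(name, ch) list(name = name, type = "bn", ch = ch)

.decoder_spec <- function(w) {
  sp <- list()
  for (i in 4:1) {
    sp <- c(sp, list(
      .spec_convt(paste0("dec", i, "_up"), w[i + 1], w[i]),
      .spec_conv(paste0("dec", i, "_c1"), 3, 3, 2 * w[i], w[i]),
      .spec_conv(paste0("dec", i, "_c2"), 3, 3, w[i], w[i])))
  }
  c(sp, list(.spec_conv("out", 1, 1, w[1], 1)))
}

.attention_spec <- function(w) {
  sp <- list()
  for (i in 1:4) {
    g <- max(1L, w[i] %/% 2L)
    sp <- c(sp, list(
      .spec_conv(paste0("att", i, "_wx"), 1, 1, w[i], g),
      .spec_conv(paste0("att", i, "_wg"), 1, 1, w[i], g),
      .spec_conv(paste0("att", i, "_psi"), 1, 1, g, 1)))
  }
  sp
}

.network_spec <- function(config) {
  w <- .widths(config)
  cin <- c(config$in_channels, w[1:4])
  sp <- list()
  if (config$architecture %in% c("unet", "attention_unet")) {
    for (i in 1:5) {
      sp <- c(sp, list(
        .spec_conv(paste0("enc", i, "_c1"), 3, 3, cin[i], w[i]),
        .spec_conv(paste0("enc", i, "_c2"), 3, 3, w[i], w[i])))
    }
  } else if (config$architecture == "dense_unet") {
    # dense block: growth rate = level width; two conv->BN->ReLU layers with
    # concatenative connectivity, then a 1x1 transition to the level width
    for (i in 1:5) {
      sp <- c(sp, list(
        .spec_conv(paste0("enc", i, "_d1"), 3, 3, cin[i], w[i]),
        .spec_bn(paste0("enc", i, "_bn1"), w[i]),
        .spec_conv(paste0("enc", i, "_d2"), 3, 3, cin[i] + w[i], w[i]),
        .spec_bn(paste0("enc", i, "_bn2"), w[i]),
        .spec_conv(paste0("enc", i, "_tr"), 1, 1, cin[i] + 2L * w[i], w[i])))
    }
  } else {  # residual_attention_unet
    # two residual units per level; the first projects channels with a 1x1
    # shortcut, the second uses an identity shortcut
    for (i in 1:5) {
      sp <- c(sp, list(
        .spec_conv(paste0("enc", i, "_r1c1"), 3, 3, cin[i], w[i]),
        .spec_conv(paste0("enc", i, "_r1c2"), 3, 3, w[i], w[i]),
        .spec_conv(paste0("enc", i, "_r1sc"), 1, 1, cin[i], w[i]),
        .spec_conv(paste0("enc", i, "_r2c1"), 3, 3, w[i], w[i]),
        .spec_conv(paste0("enc", i, "_r2c2"), 3, 3, w[i], w[i])))
    }
  }
  if (config$architecture == "residual_attention_unet") {
    # decoder also residual, with attention-gated skips
    for (i in 4:1) {
      sp <- c(sp, list(
        .spec_convt(paste0("dec", i, "_up"), w[i + 1], w[i]),
        .spec_conv(paste0("dec", i, "_r1c1"), 3, 3, 2 * w[i], w[i]),
        .spec_conv(paste0("dec", i, "_r1c2"), 3, 3, w[i], w[i]),
        .spec_conv(paste0("dec", i, "_r1sc"), 1, 1, 2 * w[i], w[i]),
        .spec_conv(paste0("dec", i, "_r2c1"), 3, 3, w[i], w[i]),
        .spec_conv(paste0("dec", i, "_r2c2"), 3, 3, w[i], w[i])))
    }
    sp <- c(sp, list(.spec_conv("out", 1, 1, w[1], 1)), .attention_spec(w))
  } else {
    sp <- c(sp, .decoder_spec(w))
    if (config$architecture == "attention_unet")
      sp <- c(sp, .attention_spec(w))
  }
  sp
}

# fan-in uniform initialization
.init_params <- function(spec, seed) {
  set.seed(as.integer(seed))
  params <- list()
  bn <- list()
  for (s in spec) {
    if (s$type == "bn") {
      params[[paste0(s$name, ".g")]] <- rep(1, s$ch)
      params[[paste0(s$name, ".b")]] <- rep(0, s$ch)
      st <- new.env(parent = emptyenv())
      st$running_mean <- rep(0, s$ch)
      st$running_var <- rep(1, s$ch)
      bn[[s$name]] <- st
    } else {
      fan_in <- s$kh * s$kw * s$cin
      lim <- sqrt(6 / fan_in)
      params[[paste0(s$name, ".w")]] <-
        array(stats::runif(s$kh * s$kw * s$cin * s$cout, -lim, lim),
              c(s$kh, s$kw, s$cin, s$cout))
      params[[paste0(s$name, ".b")]] <- rep(0, s$cout)
    }
  }
  list(params = params, bn = bn)
}

#' Build a segmentation network
#'
#' Constructs one of the four encoder-decoder architectures with seeded
#' fan-in uniform weight initialization. The forward contract is: 3-channel
#' image in \[0, 1\] in, per-pixel infarct probability (sigmoid) out, same
#' spatial shape.
#'
#' @param config `network_config`
#' @return object of class `segmentation_model`
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  spec <- .network_spec(config)
  ini <- .init_params(spec, config$seed)
  structure(list(config = config, params = ini$params, bn = ini$bn,
                 spec = spec),
            class = "segmentation_model")
}

#' @rdname build_network
#' @export
build_unet <- function(config = network_config("unet")) {
  config$architecture <- "unet"
  build_network(config)
}

#' @rdname build_network
#' @export
build_attention_unet <- function(config = network_config("attention_unet")) {
  config$architecture <- "attention_unet"
  build_network(config)
}

#' @rdname build_network
#' @export
build_dense_unet <- function(config = network_config("dense_unet")) {
  config$architecture <- "dense_unet"
  build_network(config)
}

#' @rdname build_network
#' @export
build_residual_attention_unet <-
  function(config = network_config("residual_attention_unet")) {
  config$architecture <- "residual_attention_unet"
  build_network(config)
}

#' Number of trainable parameters
#'
#' Counts every weight, bias and batch-normalization scale/shift (running
#' statistics are not trainable).
#'
#' @param model `segmentation_model` or `multifidelity_model`
#' @return integer count
#' @export
count_parameters <- function(model) {
  if (inherits(model, "multifidelity_model"))
    return(count_parameters(model$nn_lf) +
             sum(lengths(model$hf_params)))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("%s: input %dx%dx%d, base width %d, %s trainable parameters\n",
              x$config$architecture, x$config$input_size,
              x$config$input_size, x$config$in_channels,
              x$config$base_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- forward passes --------------------------------------------------------

.p <- function(pn, name) pn[[name]]

.conv_relu <- function(tp, pn, name, x, pad = c(1L, 1L, 1L, 1L)) {
  ag_relu(tp, ag_conv2d(tp, x, .p(pn, paste0(name, ".w")),
                        .p(pn, paste0(name, ".b")), 1L, pad))
}

.conv_plain <- function(tp, pn, name, x, pad = c(1L, 1L, 1L, 1L)) {
  ag_conv2d(tp, x, .p(pn, paste0(name, ".w")), .p(pn, paste0(name, ".b")),
            1L, pad)
}

.conv1x1 <- function(tp, pn, name, x)
  .conv_plain(tp, pn, name, x, pad = c(0L, 0L, 0L, 0L))

.att_gate <- function(tp, pn, i, skip, gate) {
  q <- ag_relu(tp, ag_add(tp, .conv1x1(tp, pn, paste0("att", i, "_wx"), skip),
                          .conv1x1(tp, pn, paste0("att", i, "_wg"), gate)))
  alpha <- ag_sigmoid(tp, .conv1x1(tp, pn, paste0("att", i, "_psi"), q))
  ag_scale_channels(tp, skip, alpha)
}

.res_block <- function(tp, pn, name, x, project) {
  h <- .conv_relu(tp, pn, paste0(name, "c1"), x)
  h <- .conv_plain(tp, pn, paste0(name, "c2"), h)
  s <- if (project) .conv1x1(tp, pn, paste0(name, "sc"), x) else x
  ag_relu(tp, ag_add(tp, h, s))
}

.dense_block <- function(tp, pn, model, i, x, training) {
  bn1 <- model$bn[[paste0("enc", i, "_bn1")]]
  bn2 <- model$bn[[paste0("enc", i, "_bn2")]]
  h1 <- ag_relu(tp, ag_batchnorm(
    tp, .conv_plain(tp, pn, paste0("enc", i, "_d1"), x),
    .p(pn, paste0("enc", i, "_bn1.g")), .p(pn, paste0("enc", i, "_bn1.b")),
    bn1, training))
  x2 <- ag_concat_c(tp, x, h1)
  h2 <- ag_relu(tp, ag_batchnorm(
    tp, .conv_plain(tp, pn, paste0("enc", i, "_d2"), x2),
    .p(pn, paste0("enc", i, "_bn2.g")), .p(pn, paste0("enc", i, "_bn2.b")),
    bn2, training))
  x3 <- ag_concat_c(tp, x2, h2)
  ag_relu(tp, .conv1x1(tp, pn, paste0("enc", i, "_tr"), x3))
}

.encode_level <- function(tp, pn, model, i, x, training) {
  arch <- model$config$architecture
  if (arch %in% c("unet", "attention_unet")) {
    h <- .conv_relu(tp, pn, paste0("enc", i, "_c1"), x)
    .conv_relu(tp, pn, paste0("enc", i, "_c2"), h)
  } else if (arch == "dense_unet") {
    .dense_block(tp, pn, model, i, x, training)
  } else {
    h <- .res_block(tp, pn, paste0("enc", i, "_r1"), x, project = TRUE)
    .res_block(tp, pn, paste0("enc", i, "_r2"), h, project = FALSE)
  }
}

.decode_level <- function(tp, pn, model, i, below, skip) {
  arch <- model$config$architecture
  up <- ag_convt2x2(tp, below, .p(pn, paste0("dec", i, "_up.w")),
                    .p(pn, paste0("dec", i, "_up.b")))
  if (arch %in% c("attention_unet", "residual_attention_unet"))
    skip <- .att_gate(tp, pn, i, skip, up)
  h <- ag_concat_c(tp, up, skip)
  if (arch == "residual_attention_unet") {
    h <- .res_block(tp, pn, paste0("dec", i, "_r1"), h, project = TRUE)
    .res_block(tp, pn, paste0("dec", i, "_r2"), h, project = FALSE)
  } else {
    h <- .conv_relu(tp, pn, paste0("dec", i, "_c1"), h)
    .conv_relu(tp, pn, paste0("dec", i, "_c2"), h)
  }
}

# full forward pass; returns the sigmoid output node
.forward_network <- function(tp, pn, model, x_node, training = FALSE) {
  skips <- vector("list", 4)
  h <- x_node
  for (i in 1:4) {
    skips[[i]] <- .encode_level(tp, pn, model, i, h, training)
    h <- ag_maxpool2(tp, skips[[i]])
  }
  h <- .encode_level(tp, pn, model, 5, h, training)
  for (i in 4:1) h <- .decode_level(tp, pn, model, i, h, skips[[i]])
  ag_sigmoid(tp, .conv1x1(tp, pn, "out", h))
}

#' Per-pixel infarct probabilities
#'
#' @param model `segmentation_model`
#' @param x input array `[H, W, 3, N]` (or a single `[H, W, 3]` image, or a
#'   `bullseye_image`)
#' @param chunk maximum batch chunk evaluated at once
#' @return array `[H, W, 1, N]` of probabilities in (0, 1)
#' @export
predict_probs <- function(model, x, chunk = 8L) {
  x <- .as_batch(x)
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input size must be divisible by 16")
  N <- d[4]
  out <- array(0, c(d[1], d[2], 1, N))
  for (s in seq(1, N, by = chunk)) {
    e <- min(s + chunk - 1, N)
    tp <- ag_tape()
    pn <- lapply(model$params, ag_const)
    xn <- ag_const(x[, , , s:e, drop = FALSE])
    out[, , , s:e] <- .forward_network(tp, pn, model, xn,
                                       training = FALSE)$val
  }
  out
}

.as_batch <- function(x) {
  if (inherits(x, "bullseye_image")) x <- x$pixels
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  x
}

#' Binarize predicted probabilities into an infarct mask
#'
#' @param model `segmentation_model` (or `multifidelity_model`)
#' @param image input image / batch
#' @param threshold probability threshold in (0, 1), default 0.5
#' @return binary array of the input spatial shape
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  p <- if (inherits(model, "multifidelity_model"))
    predict_multifidelity(model, image) else predict_probs(model, image)
  (p >= threshold) + 0L
}

#' Save / load a model checkpoint
#'
#' Weights are stored as an RDS file with a JSON architecture sidecar.
#'
#' @param model `segmentation_model`
#' @param path RDS path; the sidecar is written next to it as
#'   `<path>.json`
#' @return `path` (`save_checkpoint`) or the model (`load_checkpoint`)
#' @export
save_checkpoint <- function(model, path) {
  snap <- model
  snap$bn <- lapply(model$bn, as.list)
  saveRDS(snap, path)
  writeLines(jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  snap <- readRDS(path)
  snap$bn <- lapply(snap$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- st$running_mean
    e$running_var <- st$running_var
    e
  })
  snap
}
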