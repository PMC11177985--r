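# Network construction, parameter counts, forward contracts, and the
# correctness of the autodiff engine on a full network.

test_that("base UNet reproduces the reference parameter count", {
  m <- build_unet(network_config("unet", 128, base_channels = 16))
  expect_identical(count_parameters(m), 1941105)
  expect_equal(round(count_parameters(m) / 1e6, 2), 1.94)
})

test_that("parameter counts increase across the architecture variants", {
  counts <- vapply(c("unet", "attention_unet", "dense_unet",
                     "residual_attention_unet"), function(a)
    count_parameters(build_network(network_config(a, 128,
                                                  base_channels = 16))),
    numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_gt(counts["attention_unet"], 1941105)
  expect_equal(unname(which.max(counts)), 4L)  # residual attention largest
})

test_that("dense blocks concatenate features before each convolution", {
  cfg <- network_config("dense_unet", 64, base_channels = 8)
  m <- build_dense_unet(cfg)
  spec <- m$spec
  byname <- stats::setNames(spec, vapply(spec, `[[`, character(1), "name"))
  w <- 8 * 2^(0:4)
  cin <- c(3, w[1:4])
  for (i in 1:5) {
    expect_equal(byname[[paste0("enc", i, "_d2")]]$cin, cin[i] + w[i])
    expect_equal(byname[[paste0("enc", i, "_tr")]]$cin, cin[i] + 2 * w[i])
  }
})

test_that("forward contract: probabilities in (0,1) at the input shape", {
  set.seed(1)
  for (arch in c("unet", "attention_unet", "dense_unet",
                 "residual_attention_unet")) {
    m <- build_network(network_config(arch, 32, base_channels = 2, seed = 4))
    x <- array(stats::runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
    p <- predict_probs(m, x)
    expect_equal(dim(p), c(32, 32, 1, 2))
    expect_true(all(p > 0 & p < 1))
  }
  # zero image also satisfies the contract
  m <- build_unet(network_config("unet", 32, base_channels = 2))
  p0 <- predict_probs(m, array(0, c(32, 32, 3, 1)))
  expect_true(all(p0 > 0 & p0 < 1))
})

test_that("builds are deterministic under a fixed seed", {
  a <- build_unet(network_config("unet", 32, base_channels = 4, seed = 9))
  b <- build_unet(network_config("unet", 32, base_channels = 4, seed = 9))
  expect_identical(a$params, b$params)
  c2 <- build_unet(network_config("unet", 32, base_channels = 4, seed = 10))
  expect_false(identical(a$params, c2$params))
})

test_that("invalid input sizes are rejected", {
  expect_error(network_config("unet", 100), "divisible by 16")
  m <- build_unet(network_config("unet", 32, base_channels = 2))
  expect_error(predict_probs(m, array(0, c(30, 30, 3, 1))),
               "divisible by 16")
})

test_that("mask thresholding is monotone in the threshold", {
  m <- build_unet(network_config("unet", 32, base_channels = 2, seed = 2))
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1))
  p <- predict_probs(m, x)
  lo <- (p >= 0.3) + 0L
  hi <- (p >= 0.7) + 0L
  expect_true(all(lo >= hi))  # lowering the threshold never shrinks the mask
  expect_true(all(predict_mask(m, x, 1 - 1e-9) == 0 | p >= 1 - 1e-9))
  expect_error(predict_mask(m, x, 1.5), "threshold")

  # constructed probabilities
  expect_true(all((array(0.9, c(4, 4)) >= 0.5) + 0L == 1))
})

test_that("network gradients match finite differences end to end", {
  # tiny UNet on a 16x16 input; checks the full tape (convolutions,
  # transposed convolutions, pooling, concatenation, sigmoid)
  set.seed(21)
  m <- build_unet(network_config("unet", 16, base_channels = 2, seed = 21))
  x <- array(stats::runif(16 * 16 * 3 * 1), c(16, 16, 3, 1))
  y <- array((stats::runif(16 * 16) > 0.5) + 0, c(16, 16, 1, 1))
  lossfn <- get_loss("bce")
  st <- strain2infarct:::.train_step(m, x, y, lossfn, training = FALSE)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    p <- predict_probs(m2, x)
    lossfn$loss(p, y)
  }
  for (nm in c("enc1_c1.w", "enc3_c2.w", "dec2_up.w", "dec1_c2.b", "out.w")) {
    gan <- st$grads[[nm]]
    idx <- sample(length(gan), min(3, length(gan)))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
      num <- (loss_at(pp) - loss_at(pm)) / 2e-6
      expect_equal(gan[i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("attention and batchnorm paths are differentiable and train", {
  set.seed(3)
  lib <- tiny_library(2, seed = 13)
  imgs <- preprocess_library(lib, size = 32)
  for (arch in c("attention_unet", "dense_unet",
                 "residual_attention_unet")) {
    m <- build_network(network_config(arch, 32, base_channels = 2, seed = 3))
    m <- train_model(m, imgs, loss = "bce", epochs = 2, batch_size = 2,
                     lr = 1e-3, patience = 5, seed = 3)
    h <- attr(m, "history")
    expect_lt(h$train_loss[2], h$train_loss[1])
  }
})

test_that("one training epoch reduces the loss on a 16-example fixture", {
  sp <- tiny_dataset(4, size = 32, seed = 17, fractions = c(1, 0, 0))
  train <- sp$train[1:16]
  m <- build_unet(network_config("unet", 32, base_channels = 4, seed = 5))
  b <- images_to_batch(train)
  before <- bce_loss(predict_probs(m, b$x), b$y)
  m <- train_model(m, train, loss = "bce", epochs = 1, batch_size = 8,
                   lr = 1e-3, patience = 5, seed = 5)
  after <- bce_loss(predict_probs(m, b$x), b$y)
  expect_lt(after, before)
})

test_that("checkpoints round-trip through disk", {
  m <- build_dense_unet(network_config("dense_unet", 32, base_channels = 2,
                                       seed = 6))
  x <- array(stats::runif(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- predict_probs(m, x)
  path <- file.path(tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(predict_probs(m2, x), p1)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$architecture, "dense_unet")
})
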