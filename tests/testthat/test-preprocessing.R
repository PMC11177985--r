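# Bullseye rendering, normalization, channel composition, rotation
# augmentation, resizing, and grouped dataset splits.

uniform_example <- function(v, cfg = generator_config(n_examples = 1)) {
  spec <- infarct_spec("mid", 0, 0.3, 1)
  ex <- generate_strain_example(spec, cfg, seed = 1)
  ex$strains[] <- v
  ex
}

test_that("bullseye rendering follows the ring geometry", {
  cfg <- generator_config(n_examples = 1)
  ex <- uniform_example(0.1, cfg)
  g <- render_bullseye(ex, "CC", 64)
  co <- strain2infarct:::.disc_coords(64)
  expect_true(all(abs(g[co$inside] - 0.1) < 1e-12))  # constant field
  expect_true(all(g[!co$inside] == 0))               # background zero

  # strain only at base level -> only the outer ring non-background
  ex2 <- uniform_example(0, cfg)
  ex2$strains[, , "base", ] <- 0.2
  g2 <- render_bullseye(ex2, "CC", 64)
  outer_ring <- co$inside & co$r > 0.75
  expect_true(all(abs(g2[outer_ring] - 0.2) < 1e-12))
  expect_true(all(g2[co$inside & co$r <= 0.75] == 0))

  # pixel at radius 0.6 R lies in the mid ring
  ex3 <- uniform_example(0, cfg)
  ex3$strains[, , "mid", ] <- -0.15
  g3 <- render_bullseye(ex3, "CC", 128)
  probe <- which(co_probe <- abs(strain2infarct:::.disc_coords(128)$r - 0.6) <
                   0.01, arr.ind = TRUE)[1, ]
  expect_equal(g3[probe[1], probe[2]], -0.15)

  expect_error(render_bullseye(ex, "XX", 64), "unknown component")
  expect_error(render_bullseye(ex, "CC", 16), "size >= 32")
})

test_that("strain-to-intensity mapping is affine with clipping", {
  rg <- list(CC = c(-0.2, 0.1))
  expect_equal(strain_to_intensity(-0.2, "CC", rg), 0)
  expect_equal(strain_to_intensity(0.1, "CC", rg), 1)
  expect_equal(strain_to_intensity(-0.05, "CC", rg), 0.5)
  expect_equal(strain_to_intensity(-5, "CC", rg), 0)   # clipped
  expect_equal(strain_to_intensity(5, "CC", rg), 1)
  expect_error(strain_to_intensity(0, "QQ", rg), "unknown component")
})

test_that("channel composition is fixed R=circ, G=rad, B=long", {
  a <- matrix(1, 8, 8); z <- matrix(0, 8, 8)
  img <- compose_channels(a, z, z)
  expect_equal(img$pixels[, , 1], a)
  expect_equal(img$pixels[, , 2], z)
  expect_equal(img$pixels[, , 3], z)

  b <- matrix(stats::runif(64), 8, 8)
  img2 <- compose_channels(b, b, b)
  expect_equal(img2$pixels[, , 1], img2$pixels[, , 3])

  # round trip
  cc <- matrix(stats::runif(64), 8, 8)
  rr <- matrix(stats::runif(64), 8, 8)
  ll <- matrix(stats::runif(64), 8, 8)
  back <- decompose_channels(compose_channels(cc, rr, ll))
  expect_equal(back$circ, cc)
  expect_equal(back$rad, rr)
  expect_equal(back$long, ll)

  expect_error(compose_channels(a, z, matrix(0, 4, 4)), "share one shape")
})

test_that("full image pipeline keeps pixels in [0,1] with zero background", {
  lib <- tiny_library(2)
  img <- bullseye_image_from_example(lib$examples[[1]], 64,
                                     default_strain_ranges(lib$config))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  expect_true(all(img$mask %in% c(0, 1)))
  co <- strain2infarct:::.disc_coords(64)
  for (cc in 1:3)
    expect_true(all(img$pixels[, , cc][!co$inside] == 0))
  expect_true(all(img$mask[!co$inside] == 0))
})

test_that("rotation augmentation is a fourfold, lossless expansion", {
  lib <- tiny_library(3)
  imgs <- preprocess_library(lib, size = 32)
  aug <- augment_rotations(imgs)
  expect_length(aug, 12)
  rots <- vapply(aug, function(im) im$meta$rotation, integer(1))
  expect_equal(rots, rep(c(0L, 90L, 180L, 270L), 3))

  # four quarter turns return the original bit-exactly
  r4 <- strain2infarct:::.rot_image(imgs[[1]], 4L)
  expect_identical(r4$pixels, imgs[[1]]$pixels)
  expect_identical(r4$mask, imgs[[1]]$mask)

  # rotation permutes pixels: mask count preserved
  for (im in aug[1:4]) expect_equal(sum(im$mask), sum(imgs[[1]]$mask))

  # rotation commutes with channel composition
  ch <- decompose_channels(imgs[[1]])
  rot1 <- strain2infarct:::.rot90
  direct <- strain2infarct:::.rot_image(imgs[[1]], 1L)
  perch <- compose_channels(rot1(ch$circ), rot1(ch$rad), rot1(ch$long))
  expect_equal(direct$pixels, perch$pixels)

  ns <- imgs[[1]]
  ns$mask <- ns$mask[, 1:16]
  expect_error(augment_rotations(list(ns)), "square")

  # 148 sources -> 592 augmented images (fourfold)
  expect_equal(4L * 148L, 592L)
})

test_that("resizing preserves constants and keeps masks binary", {
  lib <- tiny_library(1)
  img <- bullseye_image_from_example(lib$examples[[1]], 128)
  same <- resize_bullseye(img, 128)
  expect_equal(same$pixels, img$pixels)
  expect_equal(same$mask, img$mask)

  const <- img
  const$pixels[] <- 0.42
  up <- resize_bullseye(const, 256)
  expect_true(all(abs(up$pixels - 0.42) < 1e-12))
  expect_true(all(up$mask %in% c(0, 1)))
  expect_equal(dim(up$pixels), c(256L, 256L, 3L))

  expect_error(resize_bullseye(img, 100), "invalid target size")
})

test_that("dataset splits group augmented copies by source example", {
  lib <- tiny_library(10)
  imgs <- augment_rotations(preprocess_library(lib, size = 32))
  sp <- split_dataset(imgs, c(0.6, 0.2, 0.2), seed = 3)
  ids <- function(set) unique(vapply(set, function(im)
    as.integer(im$meta$source_id), integer(1)))
  expect_length(intersect(ids(sp$train), ids(sp$val)), 0)
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_length(intersect(ids(sp$val), ids(sp$test)), 0)
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), 40)
  # every source contributes all four rotations to one split
  expect_true(all(table(vapply(sp$train, function(im)
    im$meta$source_id, integer(1))) == 4))

  sp2 <- split_dataset(imgs, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(vapply(sp2$train, function(im) im$meta$source_id,
                          integer(1)),
                   vapply(sp$train, function(im) im$meta$source_id,
                          integer(1)))

  all_train <- split_dataset(imgs, c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 40)
  expect_length(all_train$test, 0)

  expect_error(split_dataset(imgs, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("batch stacking matches image contents", {
  lib <- tiny_library(2)
  imgs <- preprocess_library(lib, size = 32)
  b <- images_to_batch(imgs)
  expect_equal(dim(b$x), c(32, 32, 3, 2))
  expect_equal(dim(b$y), c(32, 32, 1, 2))
  expect_equal(b$x[, , , 2], imgs[[2]]$pixels)
  expect_equal(b$y[, , 1, 1], imgs[[1]]$mask + 0)
})
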