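# Conversion of strain examples into normalized 3-channel AHA bullseye
# images with paired infarct masks, fixed-rotation augmentation, and
# grouped dataset splits.

#' Default fixed strain-to-intensity ranges
#'
#' Per-component affine normalization ranges shared by the low- and
#' high-fidelity domains, derived from the generator's healthy baselines
#' (baseline extremes with angular modulation, attenuation toward zero, and
#' noise headroom).
#'
#' @param config `generator_config`
#' @return named list of `c(min, max)` per component (`CC`, `RR`, `LL`)
#' @export
default_strain_ranges <- function(config = generator_config()) {
  out <- list()
  for (cc in STRAIN_COMPONENTS) {
    h <- config$healthy_strain[, cc] * max(config$base_model_factors) *
      (1 + config$angular_amplitude)
    lo <- min(0, min(h)) - 0.05
    hi <- max(0, max(h)) + 0.05
    out[[cc]] <- c(lo, hi)
  }
  out
}

# pixel-center polar coordinates of a size x size bullseye disc;
# angle 0 at the image +x axis, counterclockwise (+y up)
.disc_coords <- function(size) {
  ctr <- (size + 1) / 2
  R <- size / 2
  x <- matrix(rep(seq_len(size), each = size), size, size) - ctr
  y <- ctr - matrix(rep(seq_len(size), size), size, size)
  r <- sqrt(x^2 + y^2) / R
  theta <- atan2(y, x) %% (2 * pi)
  list(r = r, theta = theta, inside = r <= 1)
}

#' Render one strain component of an example as an AHA bullseye grid
#'
#' Four concentric rings carry the four short-axis levels (apex innermost
#' disc, then apical, mid, base outermost) with ring boundary radii at
#' 0.25 / 0.50 / 0.75 / 1.00 of the disc radius. Each in-disc pixel takes
#' the value of the polar-grid cell containing it; pixels outside the outer
#' ring are 0.
#'
#' @param example `strain_example`
#' @param component `"CC"`, `"RR"`, or `"LL"`
#' @param size image side length in pixels (>= 32)
#' @return `size x size` matrix of strain values
#' @export
render_bullseye <- function(example, component = "CC", size = 128L) {
  if (!component %in% STRAIN_COMPONENTS)
    stop("unknown component '", component, "'")
  stopifnot(size >= 32)
  cc <- match(component, STRAIN_COMPONENTS)
  .render_polar(example$strains[, , , cc], size)
}

#' Render an example's infarct mask on the bullseye geometry
#' @inheritParams render_bullseye
#' @return `size x size` binary matrix
#' @export
render_mask <- function(example, size = 128L) {
  out <- .render_polar(example$mask, size)
  (out > 0.5) + 0L
}

# field: [n_theta, n_rad, 4] polar values (levels base, mid, apical, apex)
.render_polar <- function(field, size) {
  nt <- dim(field)[1]; nr <- dim(field)[2]
  co <- .disc_coords(size)
  out <- matrix(0, size, size)
  r_out <- c(1.00, 0.75, 0.50, 0.25)
  r_in <- c(0.75, 0.50, 0.25, 0.00)
  jj <- pmin(floor(co$theta / (2 * pi / nt)) + 1L, nt)
  for (l in 1:4) {
    sel <- co$inside & co$r > r_in[l] & co$r <= r_out[l]
    if (l == 4) sel <- sel | (co$inside & co$r == 0)
    if (!any(sel)) next
    t_loc <- (co$r[sel] - r_in[l]) / (r_out[l] - r_in[l])
    kk <- pmin(pmax(floor(t_loc * nr) + 1L, 1L), nr)
    lv <- field[, , l]
    out[sel] <- lv[cbind(jj[sel], kk)]
  }
  out
}

#' Map a strain value to a normalized pixel intensity
#'
#' Direct monotone affine map of a fixed per-component strain range onto
#' \[0, 1\], clipped; the fixed range makes the normalization
#' dataset-independent so both fidelity domains share one mapping.
#'
#' @param value strain value(s)
#' @param component `"CC"`, `"RR"`, or `"LL"`
#' @param ranges named list of per-component `c(min, max)`
#' @return intensity in \[0, 1\], same shape as `value`
#' @export
strain_to_intensity <- function(value, component = "CC",
                                ranges = default_strain_ranges()) {
  if (!component %in% names(ranges))
    stop("unknown component '", component, "'")
  rg <- ranges[[component]]
  pmin(pmax((value - rg[1]) / (rg[2] - rg[1]), 0), 1)
}

#' Compose per-component intensity grids into a bullseye image
#'
#' Channel order is fixed: R = circumferential, G = radial,
#' B = longitudinal.
#'
#' @param circ,rad,long `H x W` intensity grids in \[0, 1\]
#' @param mask optional `H x W` binary infarct mask
#' @param meta optional list (source example id, rotation tag, ...)
#' @return object of class `bullseye_image` with fields `pixels`
#'   (`H x W x 3`), `mask`, `meta`
#' @export
compose_channels <- function(circ, rad, long, mask = NULL, meta = list()) {
  if (!all(dim(circ) == dim(rad)) || !all(dim(circ) == dim(long)))
    stop("channel grids must share one shape")
  px <- array(0, c(dim(circ), 3))
  px[, , 1] <- circ; px[, , 2] <- rad; px[, , 3] <- long
  if (is.null(mask)) mask <- matrix(0L, nrow(circ), ncol(circ))
  structure(list(pixels = px, mask = mask, meta = meta),
            class = "bullseye_image")
}

#' @rdname compose_channels
#' @param image `bullseye_image`
#' @return `decompose_channels`: list of the three intensity grids
#' @export
decompose_channels <- function(image) {
  list(circ = image$pixels[, , 1], rad = image$pixels[, , 2],
       long = image$pixels[, , 3])
}

#' Render a strain example as a normalized 3-channel bullseye image
#'
#' @param example `strain_example`
#' @param size image side length (default 128)
#' @param ranges per-component normalization ranges
#' @param id source example id stored in `meta`
#' @return `bullseye_image`
#' @export
bullseye_image_from_example <- function(example, size = 128L,
                                        ranges = default_strain_ranges(),
                                        id = NA_integer_) {
  grids <- lapply(STRAIN_COMPONENTS, function(cc)
    strain_to_intensity(render_bullseye(example, cc, size), cc, ranges))
  co <- .disc_coords(size)
  grids <- lapply(grids, function(g) g * co$inside)  # background exactly 0
  compose_channels(grids[[1]], grids[[2]], grids[[3]],
                   mask = render_mask(example, size),
                   meta = list(source_id = id, rotation = 0L,
                               domain = example$domain))
}

#' Convert a strain library to bullseye images
#'
#' @param library `strain_library`
#' @param size image side length
#' @param ranges per-component normalization ranges (defaults derived from
#'   the library's own generator configuration)
#' @return list of `bullseye_image`, `meta$source_id` set from the manifest
#' @export
preprocess_library <- function(library, size = 128L, ranges = NULL) {
  stopifnot(inherits(library, "strain_library"))
  if (is.null(ranges)) ranges <- default_strain_ranges(library$config)
  lapply(seq_along(library$examples), function(i)
    bullseye_image_from_example(library$examples[[i]], size, ranges,
                                id = library$manifest$id[i]))
}

# counterclockwise 90-degree rotation of a matrix
.rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

.rot_image <- function(img, times) {
  px <- img$pixels; mk <- img$mask
  for (k in seq_len(times)) {
    px2 <- array(0, dim(px))
    for (cc in 1:3) px2[, , cc] <- .rot90(px[, , cc])
    px <- px2
    mk <- .rot90(mk)
  }
  out <- img
  out$pixels <- px
  out$mask <- mk
  out$meta$rotation <- (90L * times) %% 360L
  out
}

#' Fixed-rotation augmentation
#'
#' Each image contributes its original orientation plus rotations by 90,
#' 180 and 270 degrees (masks rotated identically): a fourfold increase in
#' dataset size.
#'
#' @param images list of `bullseye_image` (square)
#' @return list of length `4 * length(images)`
#' @export
augment_rotations <- function(images) {
  if (inherits(images, "bullseye_image")) images <- list(images)
  out <- vector("list", 4L * length(images))
  j <- 0L
  for (img in images) {
    if (nrow(img$mask) != ncol(img$mask))
      stop("rotation augmentation requires square images")
    for (t2 in 0:3) {
      j <- j + 1L
      out[[j]] <- if (t2 == 0) img else .rot_image(img, t2)
    }
  }
  out
}

# bilinear resample of a matrix to a square target (pixel-center aligned;
# identity when sizes match)
.resize_bilinear <- function(m, target) {
  S <- nrow(m)
  pos <- (seq_len(target) - 0.5) * S / target + 0.5
  i0 <- pmin(pmax(floor(pos), 1L), S)
  i1 <- pmin(i0 + 1L, S)
  w1 <- pmin(pmax(pos - i0, 0), 1)
  w0 <- 1 - w1
  rows <- m[i0, , drop = FALSE] * w0 + m[i1, , drop = FALSE] * w1
  t(t(rows[, i0, drop = FALSE]) * w0 + t(rows[, i1, drop = FALSE]) * w1)
}

.resize_nearest <- function(m, target) {
  S <- nrow(m)
  idx <- pmin(pmax(round((seq_len(target) - 0.5) * S / target + 0.5), 1L), S)
  m[idx, idx, drop = FALSE]
}

#' Resize a bullseye image
#'
#' Channels are resampled bilinearly; the mask uses nearest-neighbor and is
#' re-binarized.
#'
#' @param image `bullseye_image`
#' @param size target side length, one of 128, 256, 512
#' @return resized `bullseye_image`
#' @export
resize_bullseye <- function(image, size) {
  if (!size %in% c(128L, 256L, 512L))
    stop("invalid target size ", size, "; must be 128, 256 or 512")
  out <- image
  px <- array(0, c(size, size, 3))
  for (cc in 1:3) px[, , cc] <- .resize_bilinear(image$pixels[, , cc], size)
  out$pixels <- pmin(pmax(px, 0), 1)
  out$mask <- (.resize_nearest(image$mask, size) > 0.5) + 0L
  out
}

#' Split a dataset of bullseye images by source example
#'
#' Images are grouped by `meta$source_id` so that augmented copies of one
#' source example never straddle splits; the grouping is shuffled
#' deterministically under `seed`.
#'
#' @param images list of `bullseye_image`
#' @param fractions `c(train, val, test)`, summing to 1
#' @param seed integer seed
#' @return object of class `dataset_split` with fields `train`, `val`,
#'   `test`, `fractions`, `seed`
#' @export
split_dataset <- function(images, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  ids <- vapply(images, function(im) as.integer(im$meta$source_id),
                integer(1))
  src <- unique(ids)
  set.seed(as.integer(seed))
  src <- sample(src)
  ns <- length(src)
  n_train <- round(fractions[1] * ns)
  n_val <- round(fractions[2] * ns)
  n_val <- min(n_val, ns - n_train)
  grp_train <- src[seq_len(n_train)]
  grp_val <- if (n_val > 0) src[n_train + seq_len(n_val)] else integer(0)
  grp_test <- setdiff(src, c(grp_train, grp_val))
  structure(list(train = images[ids %in% grp_train],
                 val = images[ids %in% grp_val],
                 test = images[ids %in% grp_test],
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Stack bullseye images into training arrays
#'
#' @param images list of `bullseye_image`
#' @return list with `x` (`[H, W, 3, N]`) and `y` (`[H, W, 1, N]`)
#' @export
images_to_batch <- function(images) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$pixels)
  N <- length(images)
  x <- array(0, c(d[1], d[2], 3, N))
  y <- array(0, c(d[1], d[2], 1, N))
  for (i in seq_len(N)) {
    x[, , , i] <- images[[i]]$pixels
    y[, , 1, i] <- images[[i]]$mask
  }
  list(x = x, y = y)
}

#' Write a bullseye image (and mask) as 8-bit PNG files
#'
#' @param image `bullseye_image`
#' @param path output PNG path for the 3-channel image
#' @param mask_path optional output path for the binary mask
#' @return `path`, invisibly
#' @export
write_bullseye_png <- function(image, path, mask_path = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG files")
  png::writePNG(aperm(image$pixels, c(1, 2, 3)), path)
  if (!is.null(mask_path))
    png::writePNG(image$mask + 0, mask_path)
  invisible(path)
}
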