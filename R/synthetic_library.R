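# Synthetic stand-in for the 592-example simulated strain library: Latin
# hypercube sampled infarct geometry and stiffness, phenomenological CRL
# strain fields at four short-axis levels (base, mid, apical, apex), and
# binary infarct masks, in a clean low-fidelity domain and a noisier,
# smoother high-fidelity (human-CMR-like) domain.

LV_LEVELS <- c("base", "mid", "apical", "apex")
STRAIN_COMPONENTS <- c("CC", "RR", "LL")

#' Generator configuration
#'
#' Defaults reproduce the library's study conditions: 592 examples cycling
#' over 4 base parameter sets (emulating hearts at 1-4 weeks post-infarct),
#' infarct size fractions Latin-hypercube sampled in \[0.05, 0.60\] and
#' region stiffness multipliers in \[0.7, 1.3\] (within 30 percent of the
#' mean).
#'
#' Healthy end-systolic baselines are level-dependent constants per strain
#' component (circumferential and longitudinal negative, radial positive),
#' modulated by a smooth angular variation. Inside the infarct each
#' component is attenuated toward zero with severity
#' `s = s0 + s1 * (stiffness_multiplier - 0.7) / 0.6` (stiffer scar
#' contracts less), through a sigmoid border zone in geodesic distance on
#' the bullseye disc. Zero-mean spatially correlated Gaussian noise is
#' added; the high-fidelity domain is additionally smoothed, amplitude
#' biased, and carries extra correlated noise, emulating strain
#' quantification from human CMR.
#'
#' @param n_examples library size (default 592)
#' @param n_base_models number of base parameter sets cycled over (default 4)
#' @param n_theta,n_rad polar grid resolution per short-axis level
#' @param healthy_strain 4 x 3 matrix of healthy baseline strains
#'   (rows = base/mid/apical/apex, columns = CC/RR/LL, dimensionless)
#' @param base_model_factors per-base-model global strain scale (length
#'   `n_base_models`), emulating progressively depressed function post-MI
#' @param angular_amplitude relative amplitude of the smooth angular
#'   modulation of the healthy baseline
#' @param severity_s0,severity_s1 attenuation mapping constants; severity at
#'   stiffness multiplier m is `s0 + s1 * (m - 0.7) / 0.6`
#' @param ecc_bulge optional small positive circumferential offset inside
#'   the infarct (dyskinetic bulge), default 0
#' @param border_zone_width sigmoid border-zone width, in units of the
#'   bullseye disc radius
#' @param noise_amplitude standard deviation of the correlated strain noise
#' @param noise_corr_length correlation length of the noise, in grid cells
#' @param hf_smooth_sigma,hf_amp_bias,hf_noise_amplitude high-fidelity
#'   domain shift: Gaussian smoothing sigma (grid cells), multiplicative
#'   amplitude bias, extra correlated-noise amplitude
#' @param size_bounds,stiffness_bounds LHS sampling intervals
#' @param seed integer seed for all sampling
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_examples = 592L,
                             n_base_models = 4L,
                             n_theta = 96L,
                             n_rad = 6L,
                             healthy_strain = NULL,
                             base_model_factors = c(1.00, 0.95, 0.90, 0.85),
                             angular_amplitude = 0.10,
                             severity_s0 = 0.55,
                             severity_s1 = 0.35,
                             ecc_bulge = 0,
                             border_zone_width = 0.08,
                             noise_amplitude = 0.010,
                             noise_corr_length = 4,
                             hf_smooth_sigma = 1.5,
                             hf_amp_bias = 0.9,
                             hf_noise_amplitude = 0.015,
                             size_bounds = c(0.05, 0.60),
                             stiffness_bounds = c(0.7, 1.3),
                             seed = 1L) {
  if (is.null(healthy_strain)) {
    healthy_strain <- cbind(CC = c(-0.12, -0.13, -0.14, -0.15),
                            RR = c(0.30, 0.32, 0.34, 0.36),
                            LL = c(-0.10, -0.11, -0.12, -0.13))
    rownames(healthy_strain) <- LV_LEVELS
  }
  stopifnot(n_examples >= 1, n_base_models >= 1,
            length(base_model_factors) >= n_base_models,
            all(dim(healthy_strain) == c(4, 3)),
            size_bounds[1] > 0, size_bounds[2] < 1,
            diff(size_bounds) > 0, diff(stiffness_bounds) > 0)
  structure(list(n_examples = as.integer(n_examples),
                 n_base_models = as.integer(n_base_models),
                 n_theta = as.integer(n_theta), n_rad = as.integer(n_rad),
                 healthy_strain = healthy_strain,
                 base_model_factors = base_model_factors,
                 angular_amplitude = angular_amplitude,
                 severity_s0 = severity_s0, severity_s1 = severity_s1,
                 ecc_bulge = ecc_bulge,
                 border_zone_width = border_zone_width,
                 noise_amplitude = noise_amplitude,
                 noise_corr_length = noise_corr_length,
                 hf_smooth_sigma = hf_smooth_sigma,
                 hf_amp_bias = hf_amp_bias,
                 hf_noise_amplitude = hf_noise_amplitude,
                 size_bounds = size_bounds,
                 stiffness_bounds = stiffness_bounds,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Latin hypercube sample
#'
#' Stratified sampling: for each dimension, exactly one sample falls in each
#' of the `n` equal-width strata of its interval. Deterministic under `seed`.
#'
#' @param n number of samples (>= 1)
#' @param bounds list of `c(lower, upper)` intervals, one per dimension
#' @param seed integer seed
#' @return `n x d` matrix of samples
#' @export
lhs_sample <- function(n, bounds, seed = 1L) {
  if (length(bounds) == 0) stop("bounds must name at least one dimension")
  if (!is.list(bounds)) bounds <- list(bounds)
  stopifnot(n >= 1)
  d <- length(bounds)
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(as.integer(n), d)
  out <- vapply(seq_len(d), function(k) {
    b <- bounds[[k]]
    b[1] + u[, k] * (b[2] - b[1])
  }, numeric(n))
  out <- matrix(out, nrow = n, ncol = d)
  colnames(out) <- names(bounds)
  out
}

#' Infarct specification
#'
#' @param center_level one of `"base"`, `"mid"`, `"apical"`, `"apex"`
#' @param center_angle seed-point angle in radians
#' @param size_fraction infarct fraction of the LV wall area, in (0, 1)
#' @param stiffness_multiplier per-region stiffness scale in \[0.7, 1.3\]
#' @return object of class `infarct_spec`
#' @export
infarct_spec <- function(center_level, center_angle, size_fraction,
                         stiffness_multiplier) {
  center_level <- match.arg(center_level, LV_LEVELS)
  if (size_fraction <= 0 || size_fraction >= 1)
    stop("size_fraction must lie in (0, 1), got ", size_fraction)
  structure(list(center_level = center_level,
                 center_angle = as.numeric(center_angle) %% (2 * pi),
                 size_fraction = size_fraction,
                 stiffness_multiplier = stiffness_multiplier),
            class = "infarct_spec")
}

#' Sample infarct specifications for a library
#'
#' Size fraction and stiffness multiplier are drawn by Latin hypercube
#' sampling over the configured bounds; infarct centers are uniform over the
#' four levels and the angle.
#'
#' @param config `generator_config`
#' @return list of `infarct_spec`, length `config$n_examples`
#' @export
sample_infarct_specs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_examples
  sm <- lhs_sample(n, list(size = config$size_bounds,
                           stiffness = config$stiffness_bounds),
                   seed = config$seed)
  set.seed(config$seed + 1L)
  lev <- sample(LV_LEVELS, n, replace = TRUE)
  ang <- stats::runif(n, 0, 2 * pi)
  lapply(seq_len(n), function(i)
    infarct_spec(lev[i], ang[i], sm[i, 1], sm[i, 2]))
}

# ---- bullseye-disc geometry of the polar grid ------------------------------
# Levels map to concentric rings (base outermost, apex innermost disc) with
# boundary radii 0.25/0.50/0.75/1.00 of the disc radius. Node (j, k, l):
# angle theta_j, radius within ring l, area weight r * dr * dtheta.
.polar_geometry <- function(config) {
  nt <- config$n_theta; nr <- config$n_rad
  theta <- (seq_len(nt) - 0.5) * 2 * pi / nt
  r_out <- c(1.00, 0.75, 0.50, 0.25)  # base, mid, apical, apex
  r_in <- c(0.75, 0.50, 0.25, 0.00)
  geo <- list()
  for (l in 1:4) {
    rr <- r_in[l] + (seq_len(nr) - 0.5) / nr * (r_out[l] - r_in[l])
    dr <- (r_out[l] - r_in[l]) / nr
    r_m <- matrix(rep(rr, each = nt), nt, nr)
    th_m <- matrix(rep(theta, nr), nt, nr)
    geo[[l]] <- list(x = r_m * cos(th_m), y = r_m * sin(th_m),
                     w = r_m * dr * (2 * pi / nt))
  }
  geo
}

# smooth a polar-grid matrix with a Gaussian kernel: circular in theta,
# reflected in r
.smooth_polar <- function(m, sigma_theta, sigma_r = sigma_theta / 2) {
  if (sigma_theta <= 0) return(m)
  nt <- nrow(m); nr <- ncol(m)
  kt <- stats::dnorm(seq(-ceiling(3 * sigma_theta), ceiling(3 * sigma_theta)),
                     sd = sigma_theta)
  kt <- kt / sum(kt)
  ht <- (length(kt) - 1) / 2
  out <- m
  # circular convolution along theta
  idx <- outer(seq_len(nt), seq(-ht, ht), function(i, s) ((i + s - 1) %% nt) + 1)
  for (c2 in seq_len(nr))
    out[, c2] <- as.vector(matrix(m[idx, c2], nt) %*% kt)
  if (sigma_r > 0 && nr > 1) {
    kr <- stats::dnorm(seq(-ceiling(3 * sigma_r), ceiling(3 * sigma_r)),
                       sd = sigma_r)
    kr <- kr / sum(kr)
    hr <- (length(kr) - 1) / 2
    ridx <- outer(seq_len(nr), seq(-hr, hr), function(i, s) {
      k <- i + s
      k[k < 1] <- 2 - k[k < 1]
      k[k > nr] <- 2 * nr - k[k > nr]
      pmin(pmax(k, 1), nr)
    })
    tmp <- out
    for (r2 in seq_len(nt))
      out[r2, ] <- as.vector(matrix(tmp[r2, ridx], nr) %*% kr)
  }
  out
}

# zero-mean correlated Gaussian field on the 4-level polar grid, unit sd
.noise_field <- function(config, corr_len) {
  nt <- config$n_theta; nr <- config$n_rad
  f <- array(stats::rnorm(nt * nr * 4), c(nt, nr, 4))
  for (l in 1:4) f[, , l] <- .smooth_polar(f[, , l], corr_len, corr_len / 2)
  sdv <- stats::sd(f)
  if (sdv > 0) f <- f / sdv
  f
}

#' Generate one synthetic strain example
#'
#' Grows the infarct from the seed point by geodesic distance on the
#' bullseye disc until the area matches `spec$size_fraction`, attenuates the
#' healthy baseline strains inside it (severity increasing with the
#' stiffness multiplier), applies a sigmoid border zone, and adds spatially
#' correlated noise. The high-fidelity domain is additionally smoothed,
#' amplitude biased, and carries extra noise.
#'
#' @param spec `infarct_spec`
#' @param config `generator_config`
#' @param domain `"low_fidelity"` or `"high_fidelity"`
#' @param seed integer seed (bit-identical output for equal `(spec, seed)`)
#' @param base_model_id integer in `1..n_base_models`
#' @return object of class `strain_example` with fields `strains`
#'   (`[n_theta, n_rad, 4, 3]`), `mask` (`[n_theta, n_rad, 4]`), `spec`,
#'   `base_model_id`, `domain`, `seed`
#' @export
generate_strain_example <- function(spec, config = generator_config(),
                                    domain = c("low_fidelity", "high_fidelity"),
                                    seed = 1L, base_model_id = 1L) {
  stopifnot(inherits(spec, "infarct_spec"), inherits(config, "generator_config"))
  domain <- match.arg(domain)
  if (spec$size_fraction <= 0 || spec$size_fraction >= 1)
    stop("size_fraction must lie in (0, 1)")
  set.seed(as.integer(seed))
  nt <- config$n_theta; nr <- config$n_rad
  geo <- .polar_geometry(config)

  # geodesic (disc Euclidean) distance from the infarct seed point
  lev_i <- match(spec$center_level, LV_LEVELS)
  r_mid <- c(0.875, 0.625, 0.375, 0.125)[lev_i]
  cx <- r_mid * cos(spec$center_angle)
  cy <- r_mid * sin(spec$center_angle)
  dist <- array(0, c(nt, nr, 4))
  wgt <- array(0, c(nt, nr, 4))
  for (l in 1:4) {
    dist[, , l] <- sqrt((geo[[l]]$x - cx)^2 + (geo[[l]]$y - cy)^2)
    wgt[, , l] <- geo[[l]]$w
  }
  total_area <- sum(wgt)
  ord <- order(dist)
  cum <- cumsum(wgt[ord])
  n_in <- which(cum >= spec$size_fraction * total_area)[1]
  if (is.na(n_in)) n_in <- length(ord)
  d_star <- dist[ord[n_in]]
  mask <- array(as.integer(dist <= d_star), c(nt, nr, 4))

  # border-zone weight: 1 deep inside, 0 far outside
  bw <- max(config$border_zone_width, 1e-6)
  w_bz <- 1 / (1 + exp((dist - d_star) / bw))

  sev <- config$severity_s0 + config$severity_s1 *
    (spec$stiffness_multiplier - 0.7) / 0.6
  sev <- min(max(sev, 0), 1)

  phase <- stats::runif(1, 0, 2 * pi)
  theta <- (seq_len(nt) - 0.5) * 2 * pi / nt
  angmod <- 1 + config$angular_amplitude * sin(theta + phase)
  bf <- config$base_model_factors[base_model_id]

  strains <- array(0, c(nt, nr, 4, 3),
                   dimnames = list(NULL, NULL, LV_LEVELS, STRAIN_COMPONENTS))
  for (l in 1:4) for (cc in 1:3) {
    base <- config$healthy_strain[l, cc] * bf * angmod  # length nt, recycled
    fld <- matrix(base, nt, nr) * (1 - sev * w_bz[, , l])
    if (cc == 1 && config$ecc_bulge > 0)
      fld <- fld + config$ecc_bulge * sev * w_bz[, , l]
    strains[, , l, cc] <- fld
  }
  if (config$noise_amplitude > 0) {
    for (cc in 1:3)
      strains[, , , cc] <- strains[, , , cc] +
        config$noise_amplitude * .noise_field(config, config$noise_corr_length)
  }
  if (domain == "high_fidelity") {
    for (l in 1:4) for (cc in 1:3)
      strains[, , l, cc] <- .smooth_polar(strains[, , l, cc],
                                          config$hf_smooth_sigma)
    strains <- strains * config$hf_amp_bias
    if (config$hf_noise_amplitude > 0) {
      for (cc in 1:3)
        strains[, , , cc] <- strains[, , , cc] +
          config$hf_noise_amplitude *
            .noise_field(config, config$noise_corr_length)
    }
  }
  structure(list(strains = strains, mask = mask, spec = spec,
                 base_model_id = as.integer(base_model_id),
                 domain = domain, seed = as.integer(seed)),
            class = "strain_example")
}

#' Area fraction of an example's infarct mask on the bullseye disc
#' @param example `strain_example`
#' @param config `generator_config` matching the example's grid
#' @return scalar in (0, 1)
#' @export
mask_area_fraction <- function(example, config = generator_config()) {
  geo <- .polar_geometry(config)
  wgt <- array(0, dim(example$mask))
  for (l in 1:4) wgt[, , l] <- geo[[l]]$w
  sum(wgt * example$mask) / sum(wgt)
}

#' Build the synthetic strain library
#'
#' Generates `config$n_examples` examples cycling round-robin over the
#' `config$n_base_models` base parameter sets, with a manifest recording
#' every specification and per-example seed.
#'
#' @param config `generator_config`
#' @param domain `"low_fidelity"` (default) or `"high_fidelity"`
#' @return object of class `strain_library`: list with `examples`,
#'   `manifest` (data frame) and `config`
#' @export
build_library <- function(config = generator_config(),
                          domain = c("low_fidelity", "high_fidelity")) {
  domain <- match.arg(domain)
  specs <- sample_infarct_specs(config)
  n <- config$n_examples
  base_ids <- ((seq_len(n) - 1L) %% config$n_base_models) + 1L
  seeds <- (config$seed * 1009L + seq_len(n)) %% .Machine$integer.max
  examples <- vector("list", n)
  for (i in seq_len(n)) {
    examples[[i]] <- generate_strain_example(specs[[i]], config, domain,
                                             seed = seeds[i],
                                             base_model_id = base_ids[i])
  }
  manifest <- data.frame(
    id = seq_len(n),
    center_level = vapply(specs, `[[`, character(1), "center_level"),
    center_angle = vapply(specs, `[[`, numeric(1), "center_angle"),
    size_fraction = vapply(specs, `[[`, numeric(1), "size_fraction"),
    stiffness_multiplier = vapply(specs, `[[`, numeric(1),
                                  "stiffness_multiplier"),
    base_model_id = base_ids,
    seed = seeds,
    domain = domain,
    stringsAsFactors = FALSE
  )
  structure(list(examples = examples, manifest = manifest, config = config),
            class = "strain_library")
}

#' @export
print.strain_library <- function(x, ...) {
  cat(sprintf(
    "Synthetic strain library: %d examples, %d base models, domain %s\n",
    nrow(x$manifest), x$config$n_base_models, x$manifest$domain[1]))
  cat(sprintf("  infarct size fraction: [%.3f, %.3f]; stiffness: [%.2f, %.2f]\n",
              min(x$manifest$size_fraction), max(x$manifest$size_fraction),
              min(x$manifest$stiffness_multiplier),
              max(x$manifest$stiffness_multiplier)))
  invisible(x)
}

#' Save / load a strain library
#'
#' The library is written as an RDS file with a CSV manifest and a JSON
#' snapshot of the generator configuration alongside it.
#'
#' @param library `strain_library`
#' @param dir output directory (created if needed)
#' @return `save_library`: the directory, invisibly. `load_library`: the
#'   `strain_library`.
#' @export
save_library <- function(library, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tryCatch({
    saveRDS(library, file.path(dir, "library.rds"))
    utils::write.csv(library$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    cfg <- library$config
    cfg$healthy_strain <- as.data.frame(cfg$healthy_strain)
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
               file.path(dir, "config.json"))
  }, error = function(e) {
    stop("failed writing library under '", dir, "': ", conditionMessage(e))
  })
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  path <- file.path(dir, "library.rds")
  if (!file.exists(path)) stop("no library found at '", path, "'")
  readRDS(path)
}
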