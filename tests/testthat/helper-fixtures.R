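# Shared fixtures: tiny libraries and datasets built in code.

tiny_library <- function(n = 8, seed = 3, domain = "low_fidelity",
                         config = NULL) {
  if (is.null(config)) config <- generator_config(n_examples = n, seed = seed)
  build_library(config, domain = domain)
}

tiny_dataset <- function(n = 8, size = 32, seed = 3,
                         fractions = c(0.7, 0.15, 0.15)) {
  lib <- tiny_library(n, seed)
  imgs <- augment_rotations(preprocess_library(lib, size = size))
  split_dataset(imgs, fractions, seed = 1)
}

random_deformation <- function(det_range = c(0.8, 1.2)) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -0.15, 0.15), 3, 3)
    d <- det(F)
    if (d >= det_range[1] && d <= det_range[2]) return(F)
  }
}

# finite-difference passive Cauchy stress assembled from numerical
# derivatives of the strain energy (independent oracle for the analytic
# stress): dW_dev/dE_bar by symmetric central differences on E_bar,
# dW_vol/dJ by central differences on J
fd_passive_cauchy <- function(F, p, frame, h = 1e-6) {
  st <- decompose_deformation(F)
  Wdev_of <- function(E_bar) {
    Ef <- t(frame$R) %*% E_bar %*% frame$R
    Q <- p$B1 * Ef[1, 1]^2 +
      p$B2 * (Ef[2, 2]^2 + Ef[3, 3]^2 + Ef[2, 3]^2) +
      p$B3 * (Ef[1, 2]^2 + Ef[1, 3]^2)
    p$c * (exp(Q) - 1)
  }
  dWdE <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    Ep <- st$E_bar; Em <- st$E_bar
    Ep[i, j] <- Ep[i, j] + h; Em[i, j] <- Em[i, j] - h
    if (i != j) { Ep[j, i] <- Ep[j, i] + h; Em[j, i] <- Em[j, i] - h }
    g <- (Wdev_of(Ep) - Wdev_of(Em)) / (2 * h)
    dWdE[i, j] <- g / ifelse(i == j, 1, 2)
    dWdE[j, i] <- dWdE[i, j]
  }
  Wvol_of <- function(J) (p$K / 2) * ((J^2 - 1) / 2 - log(J))
  dWdJ <- (Wvol_of(st$J + h) - Wvol_of(st$J - h)) / (2 * h)
  (1 / st$J) * st$F_bar %*% dWdE %*% t(st$F_bar) + dWdJ * diag(3)
}
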