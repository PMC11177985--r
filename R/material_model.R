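# Transversely isotropic hyperelastic myocardium model: Fung-type passive
# response plus fiber-aligned active contraction, evaluated at a material point.

#' Material parameters of the myocardium model
#'
#' Constants of the passive Fung-type strain-energy function
#' \eqn{W = c(e^{Q} - 1) + (K/2)((J^2-1)/2 - \ln J)} and of the active
#' fiber stress \eqn{T_a(E_f) = T_{Ca}(1 + \beta(\sqrt{2E_f+1} - 1))}.
#'
#' @param c stress-like constant (kPa, > 0)
#' @param B1,B2,B3 dimensionless anisotropy constants (> 0); `B1` weights the
#'   fiber-direction strain, `B2` the cross-fiber plane, `B3` fiber shear
#' @param K bulk modulus (kPa, > 0)
#' @param T_Ca active stress scale (kPa, >= 0); 0 in infarcted tissue, which
#'   has no contractile behavior
#' @param beta dimensionless active nonlinearity (>= 0)
#' @return object of class `material_parameters`
#' @export
material_parameters <- function(c = 0.12, B1 = 20, B2 = 8, B3 = 12,
                                K = 100, T_Ca = 0, beta = 1.5) {
  stopifnot(c > 0, B1 > 0, B2 > 0, B3 > 0, K > 0, T_Ca >= 0, beta >= 0)
  structure(list(c = c, B1 = B1, B2 = B2, B3 = B3, K = K,
                 T_Ca = T_Ca, beta = beta),
            class = "material_parameters")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("Myocardium material parameters (kPa):\n")
  cat(sprintf("  passive: c = %g, B1 = %g, B2 = %g, B3 = %g, K = %g\n",
              x$c, x$B1, x$B2, x$B3, x$K))
  cat(sprintf("  active:  T_Ca = %g, beta = %g\n", x$T_Ca, x$beta))
  invisible(x)
}

#' Serialize material parameters to / from JSON
#' @param p `material_parameters`
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return JSON string (invisibly, if written to `path`)
#' @export
material_parameters_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "material_parameters"))
  js <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname material_parameters_to_json
#' @param json JSON string or file path
#' @export
material_parameters_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(material_parameters, as.list(x))
}

#' Local fiber frame
#'
#' Orthonormal triad with `N` the local fiber direction. If `e2`/`e3` are
#' omitted they are completed by Gram-Schmidt against an arbitrary
#' non-parallel vector.
#'
#' @param N fiber direction (length-3, normalized internally)
#' @param e2,e3 optional vectors completing the triad
#' @return object of class `fiber_frame` with unit columns `N`, `e2`, `e3`
#' @export
fiber_frame <- function(N = c(1, 0, 0), e2 = NULL, e3 = NULL) {
  N <- N / sqrt(sum(N^2))
  if (is.null(e2)) {
    a <- if (abs(N[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- a - sum(a * N) * N
    e2 <- e2 / sqrt(sum(e2^2))
  } else {
    e2 <- e2 / sqrt(sum(e2^2))
  }
  if (is.null(e3)) {
    e3 <- c(N[2] * e2[3] - N[3] * e2[2],
            N[3] * e2[1] - N[1] * e2[3],
            N[1] * e2[2] - N[2] * e2[1])
  } else {
    e3 <- e3 / sqrt(sum(e3^2))
  }
  R <- cbind(N, e2, e3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-12)
    stop("fiber_frame: triad is not orthonormal")
  structure(list(N = N, e2 = e2, e3 = e3, R = R), class = "fiber_frame")
}

#' Decompose a deformation gradient
#'
#' Splits `F` into its volumetric part `J = det(F)`, the deviatoric
#' (isochoric) part `F_bar = J^{-1/3} F`, and the Green-Lagrange strains
#' `E = (F'F - I)/2` and `E_bar = (F_bar' F_bar - I)/2`.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`
#' @return object of class `deformation_state`
#' @export
decompose_deformation <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) must be > 0, got ", format(J))
  F_bar <- J^(-1 / 3) * F
  I3 <- diag(3)
  E <- (crossprod(F) - I3) / 2
  E_bar <- (crossprod(F_bar) - I3) / 2
  structure(list(F = F, J = J, F_bar = F_bar, E = E, E_bar = E_bar),
            class = "deformation_state")
}

# quadratic anisotropy exponent and its symmetric tensor gradient,
# both in the fiber frame: Q = B1 E11^2 + B2 (E22^2 + E33^2 + E23^2)
#                              + B3 (E12^2 + E13^2)
.fung_Q <- function(Ef, p) {
  p$B1 * Ef[1, 1]^2 +
    p$B2 * (Ef[2, 2]^2 + Ef[3, 3]^2 + Ef[2, 3]^2) +
    p$B3 * (Ef[1, 2]^2 + Ef[1, 3]^2)
}

.fung_dQ <- function(Ef, p) {
  G <- matrix(0, 3, 3)
  G[1, 1] <- 2 * p$B1 * Ef[1, 1]
  G[2, 2] <- 2 * p$B2 * Ef[2, 2]
  G[3, 3] <- 2 * p$B2 * Ef[3, 3]
  G[2, 3] <- G[3, 2] <- p$B2 * Ef[2, 3]
  G[1, 2] <- G[2, 1] <- p$B3 * Ef[1, 2]
  G[1, 3] <- G[3, 1] <- p$B3 * Ef[1, 3]
  G
}

#' Passive strain energy
#'
#' Deviatoric Fung-type energy `W_dev = c (exp(Q) - 1)` with the quadratic
#' exponent `Q` evaluated on the fiber-frame components of `E_bar`, and the
#' volumetric energy `W_vol = (K/2) ((J^2 - 1)/2 - ln J)`.
#'
#' @param state `deformation_state`
#' @param p `material_parameters`
#' @param frame `fiber_frame` (default: fiber along the first Cartesian axis)
#' @return list with components `W_dev` and `W_vol` (kPa)
#' @export
passive_strain_energy <- function(state, p, frame = fiber_frame()) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(p, "material_parameters"))
  Ef <- t(frame$R) %*% state$E_bar %*% frame$R
  W_dev <- p$c * (exp(.fung_Q(Ef, p)) - 1)
  J <- state$J
  W_vol <- (p$K / 2) * ((J^2 - 1) / 2 - log(J))
  list(W_dev = W_dev, W_vol = W_vol)
}

#' Active second Piola-Kirchhoff stress
#'
#' Fiber-aligned active stress
#' \eqn{S_{act} = T_a(E_f) / (2E_f + 1) \; N \otimes N} with
#' \eqn{T_a(E_f) = T_{Ca} (1 + \beta(\sqrt{2E_f+1} - 1))} and
#' \eqn{E_f = N \cdot E N} the fiber strain. Zero when `T_Ca = 0` (infarct).
#'
#' @param E 3x3 Green-Lagrange strain tensor
#' @param frame `fiber_frame`
#' @param p `material_parameters`
#' @return 3x3 symmetric tensor (kPa), rank at most 1
#' @export
active_second_pk <- function(E, frame, p) {
  N <- frame$N
  Ef <- drop(t(N) %*% E %*% N)
  s <- 2 * Ef + 1
  if (s <= 0)
    stop("unphysical fiber compression: 2*E_f + 1 = ", format(s), " <= 0")
  Ta <- p$T_Ca * (1 + p$beta * (sqrt(s) - 1))
  (Ta / s) * tcrossprod(N)
}

#' Total Cauchy stress
#'
#' Additive passive + active decomposition
#' \deqn{T = \frac{1}{J}\bar F \frac{\partial W_{dev}}{\partial \bar E}
#'        \bar F^T + \frac{\partial W_{vol}}{\partial J} I
#'        + \frac{1}{J} F S_{act} F^T.}
#' The deviatoric passive derivative is analytic,
#' \eqn{c\, e^{Q}\, \partial Q/\partial \bar E}, rotated between the fiber
#' frame and Cartesian axes; the volumetric pressure enters as
#' \eqn{(K/2)(J - 1/J)\, I}.
#'
#' @inheritParams passive_strain_energy
#' @param frame `fiber_frame`
#' @return 3x3 symmetric Cauchy stress (kPa)
#' @export
total_cauchy_stress <- function(state, frame, p) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(frame, "fiber_frame"),
            inherits(p, "material_parameters"))
  R <- frame$R
  Ef <- t(R) %*% state$E_bar %*% R
  dWdE_f <- p$c * exp(.fung_Q(Ef, p)) * .fung_dQ(Ef, p)
  dWdE <- R %*% dWdE_f %*% t(R)
  J <- state$J
  Tpass <- (1 / J) * state$F_bar %*% dWdE %*% t(state$F_bar) +
    (p$K / 2) * (J - 1 / J) * diag(3)
  S_act <- active_second_pk(state$E, frame, p)
  Tact <- (1 / J) * state$F %*% S_act %*% t(state$F)
  Tt <- Tpass + Tact
  (Tt + t(Tt)) / 2
}

#' Batch Cauchy-stress evaluation over a table of deformation gradients
#'
#' @param df data frame (or CSV path) with columns `Fij` (i, j in 1..3),
#'   the (i,j) components of each deformation gradient
#' @param p `material_parameters`
#' @param frame `fiber_frame`
#' @param out optional CSV path for the augmented table
#' @return input table with appended columns `T11,...,T33`
#' @export
batch_cauchy_stress <- function(df, p, frame = fiber_frame(), out = NULL) {
  if (is.character(df)) df <- utils::read.csv(df)
  cols <- paste0("F", outer(1:3, 1:3, paste0))
  stopifnot(all(cols %in% names(df)))
  Ts <- t(vapply(seq_len(nrow(df)), function(i) {
    F <- matrix(as.numeric(df[i, cols]), 3, 3, byrow = FALSE)
    as.vector(total_cauchy_stress(decompose_deformation(F), frame, p))
  }, numeric(9)))
  tn <- paste0("T", outer(1:3, 1:3, paste0))
  df[tn] <- Ts
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
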