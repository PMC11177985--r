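# Green-Lagrange CRL strains from per-frame displacement fields on a pixel
# grid. Registration-produced displacements are taken as given; short-axis
# slices are treated as 3-D fields with zero through-plane displacement.

#' Displacement increment between two consecutive frames
#'
#' @param u_x,u_y matrices (rows = Y, columns = X) of in-plane displacement
#'   components between two consecutive frames, in the same units as
#'   `spacing`
#' @param u_z optional through-plane component (defaults to zero: short-axis
#'   cine provides in-plane motion only)
#' @param spacing grid spacing `c(dx, dy)` (or `c(dx, dy, dz)`), > 0
#' @return object of class `displacement_increment`
#' @export
displacement_increment <- function(u_x, u_y, u_z = NULL, spacing = c(1, 1)) {
  u_x <- as.matrix(u_x); u_y <- as.matrix(u_y)
  if (is.null(u_z)) u_z <- matrix(0, nrow(u_x), ncol(u_x))
  u_z <- as.matrix(u_z)
  if (!all(dim(u_x) == dim(u_y)) || !all(dim(u_x) == dim(u_z)))
    stop("displacement components must share one grid shape")
  if (any(dim(u_x) < 3)) stop("degenerate grid: need at least 3x3 pixels")
  spacing <- rep_len(as.numeric(spacing), 2)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  structure(list(u_x = u_x, u_y = u_y, u_z = u_z, spacing = spacing),
            class = "displacement_increment")
}

# d/dX (columns) and d/dY (rows): central differences in the interior,
# one-sided first order at the borders
.ddx <- function(u, h) {
  W <- ncol(u)
  d <- matrix(0, nrow(u), W)
  d[, 2:(W - 1)] <- (u[, 3:W] - u[, 1:(W - 2)]) / (2 * h)
  d[, 1] <- (u[, 2] - u[, 1]) / h
  d[, W] <- (u[, W] - u[, W - 1]) / h
  d
}

.ddy <- function(u, h) {
  H <- nrow(u)
  d <- matrix(0, H, ncol(u))
  d[2:(H - 1), ] <- (u[3:H, ] - u[1:(H - 2), ]) / (2 * h)
  d[1, ] <- (u[2, ] - u[1, ]) / h
  d[H, ] <- (u[H, ] - u[H - 1, ]) / h
  d
}

#' Per-pixel incremental deformation gradient
#'
#' `F_i = I + grad(u)` with `F[i,j] = dx_i/dX_j`; spatial derivatives by
#' central differences (one-sided, first order, at grid borders), which are
#' exact for affine displacement fields at interior pixels.
#'
#' @param inc `displacement_increment`
#' @return array `[H, W, 3, 3]` of per-pixel deformation gradients
#' @export
incremental_gradient <- function(inc) {
  stopifnot(inherits(inc, "displacement_increment"))
  H <- nrow(inc$u_x); W <- ncol(inc$u_x)
  hx <- inc$spacing[1]; hy <- inc$spacing[2]
  Fg <- array(0, c(H, W, 3, 3))
  Fg[, , 1, 1] <- 1 + .ddx(inc$u_x, hx)
  Fg[, , 1, 2] <- .ddy(inc$u_x, hy)
  Fg[, , 2, 1] <- .ddx(inc$u_y, hx)
  Fg[, , 2, 2] <- 1 + .ddy(inc$u_y, hy)
  Fg[, , 3, 1] <- .ddx(inc$u_z, hx)
  Fg[, , 3, 2] <- .ddy(inc$u_z, hy)
  Fg[, , 3, 3] <- 1
  Fg
}

# per-pixel matrix product C = A %*% B for [H,W,3,3] fields
.pixmul <- function(A, B) {
  d <- dim(A)
  C <- array(0, d)
  for (i in 1:3) for (j in 1:3) {
    s <- A[, , i, 1] * B[, , 1, j]
    for (k in 2:3) s <- s + A[, , i, k] * B[, , k, j]
    C[, , i, j] <- s
  }
  C
}

#' Accumulate incremental deformation gradients
#'
#' Total per-pixel deformation gradient as the ordered product
#' `F = F_n %*% ... %*% F_1` (later increments left-multiplied: composition
#' of motions reads right to left).
#'
#' @param incs list of `displacement_increment` in temporal order
#' @return array `[H, W, 3, 3]`
#' @export
accumulate_deformation <- function(incs) {
  if (inherits(incs, "displacement_increment")) incs <- list(incs)
  stopifnot(length(incs) >= 1)
  Facc <- incremental_gradient(incs[[1]])
  d1 <- dim(Facc)
  if (length(incs) > 1) {
    for (k in 2:length(incs)) {
      Fi <- incremental_gradient(incs[[k]])
      if (!all(dim(Fi) == d1)) stop("increment grid shapes differ")
      Facc <- .pixmul(Fi, Facc)
    }
  }
  Facc
}

#' Per-pixel Green-Lagrange strain
#'
#' `E = (F'F - I)/2`, symmetric at every pixel and zero for any rigid motion.
#'
#' @param Ffield array `[H, W, 3, 3]` of per-pixel deformation gradients
#' @return array `[H, W, 3, 3]` of symmetric strain tensors
#' @export
green_lagrange <- function(Ffield) {
  d <- dim(Ffield)
  stopifnot(length(d) == 4, d[3] == 3, d[4] == 3)
  E <- array(0, d)
  for (i in 1:3) for (j in i:3) {
    s <- Ffield[, , 1, i] * Ffield[, , 1, j]
    for (k in 2:3) s <- s + Ffield[, , k, i] * Ffield[, , k, j]
    if (i == j) s <- s - 1
    E[, , i, j] <- s / 2
    if (i != j) E[, , j, i] <- s / 2
  }
  E
}

#' Per-pixel circumferential / radial / longitudinal frame
#'
#' Builds the orthonormal transformation field for a short-axis slice:
#' radial is the in-plane unit vector from the LV centroid through the pixel,
#' circumferential is its 90-degree counterclockwise in-plane rotation, and
#' longitudinal is the slice normal. Rows of each per-pixel `Q` are ordered
#' (circ, rad, long), so `Q E Q'` carries `E_CC`, `E_RR`, `E_LL` on its
#' diagonal.
#'
#' @param H,W grid dimensions
#' @param centroid LV centroid `c(x, y)` in pixel coordinates
#'   (column, row); defaults to the grid center
#' @return object of class `crl_frame`: array `[H, W, 3, 3]` of rotations
#' @export
crl_frame <- function(H, W, centroid = c((W + 1) / 2, (H + 1) / 2)) {
  xs <- matrix(rep(seq_len(W), each = H), H, W) - centroid[1]
  ys <- matrix(rep(seq_len(H), W), H, W) - centroid[2]
  r <- sqrt(xs^2 + ys^2)
  deg <- r < .Machine$double.eps^0.5
  rx <- ifelse(deg, 1, xs / pmax(r, .Machine$double.xmin))
  ry <- ifelse(deg, 0, ys / pmax(r, .Machine$double.xmin))
  Q <- array(0, c(H, W, 3, 3))
  # circumferential: 90 deg CCW rotation of radial in the (x, y) plane
  Q[, , 1, 1] <- -ry
  Q[, , 1, 2] <- rx
  Q[, , 2, 1] <- rx
  Q[, , 2, 2] <- ry
  Q[, , 3, 3] <- 1
  structure(Q, class = "crl_frame")
}

#' Transform Cartesian strains into the CRL frame
#'
#' `E_CRL = Q E Q'` per pixel; the diagonal of the result holds `E_CC`,
#' `E_RR`, `E_LL`.
#'
#' @param E array `[H, W, 3, 3]` of Cartesian strain tensors
#' @param frame `crl_frame` (or any per-pixel array of orthonormal rows)
#' @return array `[H, W, 3, 3]` of CRL strain tensors
#' @export
to_crl <- function(E, frame) {
  Q <- unclass(frame)
  stopifnot(all(dim(Q) == dim(E)))
  # per-pixel orthonormality: Q Q' = I
  QQt <- .pixmul(Q, aperm(Q, c(1, 2, 4, 3)))
  I4 <- array(rep(diag(3), each = prod(dim(E)[1:2])), dim(E))
  if (max(abs(QQt - I4)) > 1e-10)
    stop("frame is not orthonormal at every pixel")
  .pixmul(.pixmul(Q, E), aperm(Q, c(1, 2, 4, 3)))
}

#' Strain pipeline from displacement increments to CRL strains
#'
#' Convenience wrapper: accumulate the deformation gradient, form the
#' Green-Lagrange tensor, and rotate it into the CRL frame.
#'
#' @param incs list of `displacement_increment`
#' @param frame optional `crl_frame`; defaults to one centered on the grid
#' @return list with `F`, `E` (Cartesian) and `E_crl` arrays
#' @export
crl_strains_from_displacements <- function(incs, frame = NULL) {
  if (inherits(incs, "displacement_increment")) incs <- list(incs)
  Ff <- accumulate_deformation(incs)
  E <- green_lagrange(Ff)
  if (is.null(frame)) frame <- crl_frame(dim(E)[1], dim(E)[2])
  list(F = Ff, E = E, E_crl = to_crl(E, frame))
}
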