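# Green-Lagrange CRL strain pipeline from displacement increments.

grid_xy <- function(H, W) {
  list(X = matrix(rep(seq_len(W), each = H), H, W),
       Y = matrix(rep(seq_len(H), W), H, W))
}

# deviation of a per-pixel F field from identity
sweep_all <- function(Ff) {
  I4 <- array(rep(diag(3), each = prod(dim(Ff)[1:2])), dim(Ff))
  Ff - I4
}

test_that("incremental gradient is exact on affine and trivial fields", {
  H <- 9; W <- 11
  g <- grid_xy(H, W)

  zero <- displacement_increment(matrix(0, H, W), matrix(0, H, W))
  Fz <- incremental_gradient(zero)
  expect_equal(Fz[3, 4, , ], diag(3))
  expect_equal(max(abs(sweep_all(Fz))), 0)

  # rigid translation
  tr <- displacement_increment(matrix(2.5, H, W), matrix(-1, H, W))
  Ft <- incremental_gradient(tr)
  expect_equal(max(abs(sweep_all(Ft))), 0)

  # affine: u_x = 0.1 X -> F = diag(1.1, 1, 1) exactly (interior and border)
  af <- displacement_increment(0.1 * g$X, matrix(0, H, W))
  Fa <- incremental_gradient(af)
  for (i in c(1, 5, H)) for (j in c(1, 6, W))
    expect_equal(Fa[i, j, , ], diag(c(1.1, 1, 1)))

  # general affine with spacing
  af2 <- displacement_increment(0.05 * g$X + 0.02 * g$Y, 0.03 * g$X,
                                spacing = c(1, 1))
  Fa2 <- incremental_gradient(af2)
  expect_equal(Fa2[4, 5, 1, 1], 1.05)
  expect_equal(Fa2[4, 5, 1, 2], 0.02)
  expect_equal(Fa2[4, 5, 2, 1], 0.03)

  expect_error(displacement_increment(matrix(0, 2, 5), matrix(0, 2, 5)),
               "degenerate grid")
  expect_error(displacement_increment(matrix(0, 5, 5), matrix(0, 4, 5)),
               "share one grid shape")
})

test_that("deformation gradients accumulate by left multiplication", {
  H <- 8; W <- 8
  g <- grid_xy(H, W)
  inc <- displacement_increment(0.1 * g$X, matrix(0, H, W))

  F1 <- accumulate_deformation(list(inc))
  expect_equal(F1, incremental_gradient(inc))

  # two increments of u_x = 0.1 X: the second acts on the updated positions,
  # so the pixel-grid increment again has gradient diag(1.1,1,1) and the
  # product is diag(1.21, 1, 1)
  F2 <- accumulate_deformation(list(inc, inc))
  expect_equal(F2[4, 4, , ], diag(c(1.21, 1, 1)))

  # increment followed by its exact inverse field: F = I
  inv <- displacement_increment(-0.1 / 1.1 * g$X, matrix(0, H, W))
  Fi <- accumulate_deformation(list(inc, inv))
  expect_lt(max(abs(sweep_all(Fi))), 1e-8)

  bad <- displacement_increment(matrix(0, 4, 8), matrix(0, 4, 8))
  expect_error(accumulate_deformation(list(inc, bad)), "shapes differ")
})

test_that("green_lagrange matches closed forms and is objective", {
  H <- 6; W <- 6
  Ff <- array(rep(diag(3), each = H * W), c(H, W, 3, 3))
  expect_equal(max(abs(green_lagrange(Ff))), 0)

  Fd <- array(rep(diag(c(1.1, 1, 1)), each = H * W), c(H, W, 3, 3))
  E <- green_lagrange(Fd)
  expect_equal(E[2, 3, 1, 1], (1.1^2 - 1) / 2)
  expect_equal(E[2, 3, 2, 2], 0)

  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Fr <- array(rep(R, each = H * W), c(H, W, 3, 3))
  expect_lt(max(abs(green_lagrange(Fr))), 1e-12)
})

test_that("rigid-motion displacement sequences give zero strain", {
  H <- 12; W <- 12
  g <- grid_xy(H, W)
  th <- 0.05
  # small rigid rotation about the grid center expressed as displacements
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  u_x <- (cos(th) - 1) * (g$X - cx) - sin(th) * (g$Y - cy)
  u_y <- sin(th) * (g$X - cx) + (cos(th) - 1) * (g$Y - cy)
  inc <- displacement_increment(u_x, u_y)
  E <- green_lagrange(accumulate_deformation(list(inc)))
  expect_lt(max(abs(E)), 1e-8)
})

test_that("CRL transform preserves invariants and permutes components", {
  H <- 9; W <- 9
  fr <- crl_frame(H, W)

  # identity frame leaves the tensor unchanged
  Qid <- array(rep(diag(3), each = H * W), c(H, W, 3, 3))
  class(Qid) <- "crl_frame"
  E <- array(0, c(H, W, 3, 3))
  set.seed(2)
  for (i in 1:3) for (j in i:3) {
    v <- matrix(stats::rnorm(H * W, sd = 0.05), H, W)
    E[, , i, j] <- v; E[, , j, i] <- v
  }
  expect_equal(to_crl(E, Qid), E)

  # pixel on the +x axis from the centroid: rad = +x, circ = +y, long = +z
  Ed <- array(0, c(H, W, 3, 3))
  for (k in 1:3) Ed[, , k, k] <- c(0.3, -0.1, 0.05)[k]
  out <- to_crl(Ed, fr)
  px <- c(5, 9)  # centroid row, column to the right -> +x direction
  co_x <- px[2] - (W + 1) / 2; co_y <- (H + 1) / 2 - px[1]
  expect_true(abs(co_y) < 1e-9 && co_x > 0)
  expect_equal(out[px[1], px[2], 1, 1], -0.1, tolerance = 1e-12)  # E_CC = b
  expect_equal(out[px[1], px[2], 2, 2], 0.3, tolerance = 1e-12)   # E_RR = a
  expect_equal(out[px[1], px[2], 3, 3], 0.05, tolerance = 1e-12)  # E_LL = c

  # trace and Frobenius norm preserved at every pixel
  Ecrl <- to_crl(E, fr)
  tr_in <- E[, , 1, 1] + E[, , 2, 2] + E[, , 3, 3]
  tr_out <- Ecrl[, , 1, 1] + Ecrl[, , 2, 2] + Ecrl[, , 3, 3]
  expect_lt(max(abs(tr_in - tr_out)), 1e-10)
  fn_in <- sqrt(apply(E^2, c(1, 2), sum))
  fn_out <- sqrt(apply(Ecrl^2, c(1, 2), sum))
  expect_lt(max(abs(fn_in - fn_out)), 1e-10)

  # eigenvalues unchanged at a probe pixel
  ev_in <- sort(eigen(E[3, 7, , ], symmetric = TRUE)$values)
  ev_out <- sort(eigen(Ecrl[3, 7, , ], symmetric = TRUE)$values)
  expect_equal(ev_in, ev_out, tolerance = 1e-10)

  # non-orthonormal frame rejected
  Qbad <- Qid
  Qbad[, , 1, 1] <- 2
  class(Qbad) <- "crl_frame"
  expect_error(to_crl(E, Qbad), "not orthonormal")
})

test_that("pipeline wrapper recovers affine closed forms end to end", {
  H <- 16; W <- 16
  g <- grid_xy(H, W)
  inc <- displacement_increment(0.1 * g$X, -0.05 * g$Y)
  res <- crl_strains_from_displacements(list(inc))
  expect_equal(res$F[8, 8, , ], diag(c(1.1, 0.95, 1)))
  expect_equal(res$E[8, 8, 1, 1], (1.1^2 - 1) / 2)
  # CRL rotation preserves the trace
  expect_equal(res$E_crl[8, 8, 1, 1] + res$E_crl[8, 8, 2, 2] +
                 res$E_crl[8, 8, 3, 3],
               res$E[8, 8, 1, 1] + res$E[8, 8, 2, 2] + res$E[8, 8, 3, 3],
               tolerance = 1e-12)
})
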