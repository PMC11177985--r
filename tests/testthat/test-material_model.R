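# Fung-type passive + active myocardium model at a material point.

test_that("deformation decomposition matches closed forms", {
  st <- decompose_deformation(diag(3))
  expect_equal(st$J, 1)
  expect_equal(st$E, matrix(0, 3, 3))
  expect_equal(st$E_bar, matrix(0, 3, 3))

  st <- decompose_deformation(diag(c(1.1, 1, 1)))
  expect_equal(st$J, 1.1)
  expect_equal(st$E[1, 1], (1.1^2 - 1) / 2)
  expect_equal(st$E[2, 2], 0)
  expect_equal(det(st$F_bar), 1, tolerance = 1e-10)

  # simple shear F = I + 0.2 e1 (x) e2
  F <- diag(3); F[1, 2] <- 0.2
  st <- decompose_deformation(F)
  expect_equal(st$J, 1)
  expect_equal(st$E[1, 2], 0.1)
  expect_equal(st$E[2, 2], 0.02)
  expect_equal(st$E[1, 1], 0)

  expect_error(decompose_deformation(diag(c(-1, 1, 1))), "invalid deformation")
  expect_error(decompose_deformation(matrix(0, 3, 3)), "invalid deformation")
})

test_that("passive strain energy matches direct formula evaluation", {
  p <- material_parameters(c = 1, B1 = 2, B2 = 3, B3 = 4, K = 100)
  st <- decompose_deformation(diag(3))
  w <- passive_strain_energy(st, p)
  expect_equal(w$W_dev, 0)
  expect_equal(w$W_vol, 0)

  # J = 1, Ebar_11 = 0.1 only: Q = B1 * 0.01 = 0.02
  st2 <- st
  st2$E_bar <- diag(c(0.1, 0, 0))
  w2 <- passive_strain_energy(st2, p)
  expect_equal(w2$W_dev, exp(0.02) - 1, tolerance = 1e-12)

  # volumetric part at J = 1.2, K = 100
  st3 <- decompose_deformation(diag(rep(1.2^(1 / 3), 3)))
  w3 <- passive_strain_energy(st3, p)
  expect_equal(w3$W_vol, 50 * ((1.44 - 1) / 2 - log(1.2)), tolerance = 1e-9)
  expect_equal(w3$W_dev, 0, tolerance = 1e-12)  # pure dilation: E_bar = 0
})

test_that("volumetric energy is nonnegative with unique minimum at J = 1", {
  p <- material_parameters()
  Wv <- function(J) (p$K / 2) * ((J^2 - 1) / 2 - log(J))
  Js <- seq(0.5, 2, by = 0.01)
  expect_true(all(Wv(Js) >= -1e-12))
  dW <- function(J) (p$K / 2) * (J - 1 / J)
  expect_true(all(dW(Js[Js < 1]) < 0))
  expect_true(all(dW(Js[Js > 1]) > 0))
  expect_equal(Wv(1), 0)
})

test_that("active stress follows the contractile fiber model", {
  fr <- fiber_frame(c(1, 0, 0))
  p <- material_parameters(T_Ca = 10, beta = 1.5)

  # zero fiber strain: S_act = T_Ca N (x) N
  S0 <- active_second_pk(matrix(0, 3, 3), fr, p)
  expect_equal(S0, 10 * tcrossprod(c(1, 0, 0)))

  # infarct: no contractile behavior for any strain
  pi0 <- material_parameters(T_Ca = 0)
  E <- diag(c(0.2, -0.1, 0.05))
  expect_equal(active_second_pk(E, fr, pi0), matrix(0, 3, 3))

  # lambda = 1.1: E_f = 0.105, Ta = 10 (1 + 1.5 * 0.1) = 11.5
  E2 <- diag(c(0.105, 0, 0))
  S2 <- active_second_pk(E2, fr, p)
  expect_equal(S2[1, 1], 11.5 / 1.21, tolerance = 1e-12)
  expect_equal(S2[2, 2], 0)
  # symmetric, rank <= 1, aligned with N (x) N
  expect_equal(S2, t(S2))
  expect_equal(qr(S2)$rank, 1L)

  # unphysical fiber compression
  Ebad <- diag(c(-0.6, 0, 0))
  expect_error(active_second_pk(Ebad, fr, p), "fiber compression")
})

test_that("active fiber tension is non-decreasing in fiber strain", {
  p <- material_parameters(T_Ca = 5, beta = 2)
  Ef <- seq(-0.49, 0.6, by = 0.01)
  Ta <- p$T_Ca * (1 + p$beta * (sqrt(2 * Ef + 1) - 1))
  expect_true(all(diff(Ta) >= 0))
})

test_that("reference configuration is stress free and stress is symmetric", {
  fr <- fiber_frame(c(1, 1, 0))
  p <- material_parameters(T_Ca = 0)
  T0 <- total_cauchy_stress(decompose_deformation(diag(3)), fr, p)
  expect_lt(max(abs(T0)), 1e-10)

  # active term at identity: T = T_Ca N (x) N
  pa <- material_parameters(T_Ca = 10)
  Ta <- total_cauchy_stress(decompose_deformation(diag(3)), fr, pa)
  expect_equal(Ta, 10 * tcrossprod(fr$N), tolerance = 1e-10)

  set.seed(7)
  for (k in 1:20) {
    F <- random_deformation()
    Tt <- total_cauchy_stress(decompose_deformation(F), fr, pa)
    expect_lt(max(abs(Tt - t(Tt))), 1e-10)
  }
})

test_that("analytic passive stress matches the finite-difference oracle", {
  set.seed(11)
  fr <- fiber_frame(c(1, 0.3, -0.2))
  p <- material_parameters(c = 0.5, B1 = 12, B2 = 6, B3 = 9, K = 80,
                           T_Ca = 0)
  worst <- 0
  for (k in 1:100) {
    F <- random_deformation()
    Tan <- total_cauchy_stress(decompose_deformation(F), fr, p)
    Tfd <- fd_passive_cauchy(F, p, fr)
    rel <- max(abs(Tan - Tfd)) / max(max(abs(Tfd)), 1e-8)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("parameters serialize to JSON and batch evaluation round-trips", {
  p <- material_parameters(c = 0.3, B1 = 11, B2 = 5, B3 = 7, K = 55,
                           T_Ca = 2.5, beta = 1.2)
  p2 <- material_parameters_from_json(material_parameters_to_json(p))
  expect_equal(unclass(p), unclass(p2))

  tf <- file.path(tempdir(), "mp.json")
  material_parameters_to_json(p, tf)
  expect_equal(unclass(material_parameters_from_json(tf)), unclass(p))

  set.seed(5)
  Fs <- t(replicate(4, as.vector(random_deformation())))
  df <- as.data.frame(Fs)
  names(df) <- paste0("F", outer(1:3, 1:3, paste0))
  out <- batch_cauchy_stress(df, p)
  expect_true(all(paste0("T", outer(1:3, 1:3, paste0)) %in% names(out)))
  F1 <- matrix(Fs[1, ], 3, 3)
  T1 <- total_cauchy_stress(decompose_deformation(F1), fiber_frame(), p)
  expect_equal(as.numeric(out[1, paste0("T", outer(1:3, 1:3, paste0))]),
               as.vector(T1))

  csv <- file.path(tempdir(), "stress.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  out2 <- batch_cauchy_stress(csv, p)
  expect_equal(out2$T11, out$T11)

  expect_error(material_parameters(c = -1), "c > 0")
})

test_that("fiber frames are orthonormal", {
  for (v in list(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1), c(-0.2, 0.9, 0.4))) {
    fr <- fiber_frame(v)
    expect_lt(max(abs(crossprod(fr$R) - diag(3))), 1e-12)
    expect_equal(sum(fr$N^2), 1, tolerance = 1e-12)
  }
})
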