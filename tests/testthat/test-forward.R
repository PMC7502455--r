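test_that("Cauchy push-forward is correct and symmetric", {
  S <- random_spd()
  expect_equal(cauchy_from_pk2(diag(3), S), S)
  set.seed(61)
  F <- random_isochoric_F()
  expect_equal(cauchy_from_pk2(F, diag(3)), tcrossprod(F), tolerance = 1e-12)
  sig <- cauchy_from_pk2(F, random_spd())
  expect_lt(max(abs(sig - t(sig))), 1e-14 * max(abs(sig)))
})

test_that("mesh weights integrate the disc area", {
  r <- 0.0105
  rm <- radial_mesh(r)
  expect_lt(abs(sum(rm$w_area) - pi * r^2) / (pi * r^2), 1e-10)
  tm <- disc_mesh(r)
  expect_identical(tm$n_elements, 765L)
  expect_lt(abs(sum(tm$w_area) - pi * r^2) / (pi * r^2), 1e-3)
})

test_that("torque of the analytic torsion field equals pi r^4 c / 2", {
  cc <- 2.7; r <- 0.9
  f <- function(x1, x2) {
    matrix(c(0, 0, -cc * x2, 0, 0, cc * x1, -cc * x2, cc * x1, 0), 3, 3)
  }
  exact <- pi * r^4 * cc / 2
  expect_lt(abs(integrate_torque(radial_mesh(r), f) - exact) / exact, 1e-6)
  expect_lt(abs(integrate_torque(disc_mesh(r), f) - exact) / exact, 0.005)
  zero <- function(x1, x2) matrix(0, 3, 3)
  expect_equal(integrate_torque(radial_mesh(r), zero), 0)
})

test_that("triangulated and radial quadratures agree on a smooth field", {
  f <- function(x1, x2) {
    s23 <- x1 * exp(-(x1^2 + x2^2)); s13 <- -x2 * exp(-(x1^2 + x2^2))
    matrix(c(0, 0, s13, 0, 0, s23, s13, s23, 0), 3, 3)
  }
  tr <- integrate_torque(radial_mesh(1), f)
  tt <- integrate_torque(disc_mesh(1), f)
  expect_lt(abs(tt - tr) / abs(tr), 0.005)
})

test_that("mesh refinement leaves the simulated torque unchanged", {
  cond <- quick_cond(shear = 0.5, cs = 0.2)
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  t16 <- simulate_test(p, cond, radial_mesh(cond$geometry$r, order = 16))
  t32 <- simulate_test(p, cond, radial_mesh(cond$geometry$r, order = 32))
  expect_lt(max(abs(t16$tau - t32$tau)) / max(abs(t32$tau)), 1e-6)
})

test_that("simulate_test agrees with the slow general-tensor route", {
  cond <- quick_cond(cs = 0.2, shear = 0.5, Tp = 32, burnin = 2, record = 1)
  pars <- list(
    material_parameters("vmr", delta = 200, alpha = 0.25, C_lin = 150),
    material_parameters("vog", delta = 200, alpha = 0.25, b = 4),
    material_parameters("vexp", delta = 200, alpha = 0.25, b = 1.3)
  )
  for (p in pars) {
    fast <- simulate_test(p, cond)
    ref <- reference_simulate(p, cond)
    expect_lt(max(abs(fast$tau_v - ref$tau_v)) / max(abs(ref$tau_v)), 1e-12)
    if (p$model == "vmr") {
      expect_lt(max(abs(fast$tau_e - ref$tau_e)) / max(abs(ref$tau_e)), 1e-12)
    }
  }
})

test_that("degenerate loadings give zero torque", {
  # gamma = 0: pure static preload, axisymmetric stress has no 13/23 moment
  cond0 <- quick_cond(shear = 0)
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  tr <- simulate_test(p, cond0)
  expect_true(all(abs(tr$tau) < 1e-20))
  # zero linear parameters
  p0 <- material_parameters("vog", delta = 0, alpha = 0.2, b = 4)
  tr0 <- simulate_test(p0, quick_cond(shear = 0.25))
  expect_true(all(tr0$tau == 0))
})

test_that("torque is odd in the shear amplitude and free of even harmonics", {
  # odd symmetry at the stress level: flipping the shear flips the 13/23
  # stress components and leaves 33 unchanged, for every kernel, to machine
  # precision -- hence the torque is odd in gamma
  cond <- quick_cond(cs = 0.1, shear = 0.4)
  g <- cond$geometry
  pt <- material_point(g$r / 2, 0, g$H)
  Fp <- deformation_gradient(pt, cond, 0.11)          # psi(0.11) > 0
  Fm <- deformation_gradient(pt, cond, 1 - 0.11)      # psi mirrored: -psi
  expect_equal(crossprod(Fm)[2, 3], -crossprod(Fp)[2, 3], tolerance = 1e-14)
  for (m in c("vmr", "vog", "vexp")) {
    Sp <- viscoelastic_kernel(m, deformation_state(Fp), 1.3)
    Sm <- viscoelastic_kernel(m, deformation_state(Fm), 1.3)
    expect_equal(Sm[2, 3], -Sp[2, 3], tolerance = 1e-13)
    expect_equal(Sm[3, 3], Sp[3, 3], tolerance = 1e-13)
  }
  # consequence: the steady-state torque carries no even harmonics
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  geo <- sample_geometry(3e-3, 10e-3, 0.1)
  up <- simulate_test(p, test_condition(geo, 0.25, 1, 64, 8, 2))
  h <- fourier_harmonics(up$time, up$tau, 1, n_harmonics = 6)
  even <- h$amplitude[c(2, 4, 6)]
  expect_lt(max(even) / h$amplitude[1], 1e-3)
})

test_that("small-strain response is linear with the fractional phase and gain", {
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  geo <- sample_geometry(3e-3, 10e-3, 0.1)
  tr05 <- simulate_test(p, test_condition(geo, 0.001, 0.5))
  tr2 <- simulate_test(p, test_condition(geo, 0.001, 2))
  expect_lt(harmonic_distortion(tr2$time, tr2$tau, 2), 0.01)
  h05 <- fourier_harmonics(tr05$time, tr05$tau, 0.5)
  h2 <- fourier_harmonics(tr2$time, tr2$tau, 2)
  expect_lt(abs(h2$phase[1] - 0.2 * pi / 2), 0.02)
  expect_equal(h2$amplitude[1] / h05$amplitude[1], 4^0.2, tolerance = 0.02)
})

test_that("eight burn-in cycles reach a steady recorded state", {
  p <- material_parameters("vog", delta = 300, alpha = 0.2, b = 4)
  cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), 0.5, 1,
                         points_per_period = 100, n_burnin = 8, n_record = 3)
  tr <- simulate_test(p, cond)
  Tp <- 100
  last <- tr$tau[(2 * Tp + 1):(3 * Tp)]
  prev <- tr$tau[(Tp + 1):(2 * Tp)]
  expect_lt(sqrt(mean((last - prev)^2)) / sqrt(mean(last^2)), 0.005)
})

test_that("harmonic distortion grows monotonically with shear amplitude", {
  geo <- sample_geometry(3e-3, 10e-3, 0.1)
  for (m in c("vog", "vexp")) {
    p <- if (m == "vog") material_parameters(m, delta = 300, alpha = 0.2, b = 6)
         else material_parameters(m, delta = 300, alpha = 0.2, b = 1.3)
    thd <- vapply(c(0.01, 0.10, 0.25, 0.50), function(g) {
      tr <- simulate_test(p, test_condition(geo, g, 1, 100, 4, 2))
      harmonic_distortion(tr$time, tr$tau, 1)
    }, numeric(1))
    expect_true(all(diff(thd) > 0))
  }
})
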