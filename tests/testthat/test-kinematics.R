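test_that("sample geometry conserves volume under ideal compression", {
  geo <- sample_geometry(3e-3, 10e-3, 0.2)
  expect_equal(geo$h * geo$r^2, geo$H * geo$R^2)
  expect_equal(geo$lam, 0.8)
  expect_error(sample_geometry(3e-3, 10e-3, 1), "fraction")
  expect_error(sample_geometry(3e-3, 10e-3, -0.1), "fraction")
})

test_that("angular displacement follows sin(2 pi f t) h gamma / r", {
  cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), 0.5, 1)
  expect_equal(angular_displacement(cond, 0), 0)
  # f = 1, t = 1/4, H = 3 mm, R = 10 mm, cs = 10%, gamma = 0.5:
  # psi = 0.5 * 0.0027 / (0.01 / sqrt(0.9))
  expect_equal(angular_displacement(cond, 0.25),
               0.5 * 0.9 * 3e-3 / (10e-3 / sqrt(0.9)), tolerance = 1e-12)
  expect_equal(angular_displacement(cond, 0.25), 0.1280722, tolerance = 1e-6)
  # max over a period equals h gamma / r
  tt <- seq(0, 1, by = 1e-3)
  expect_equal(max(angular_displacement(cond, tt)),
               cond$geometry$h * 0.5 / cond$geometry$r, tolerance = 1e-5)
  # zero shear => identically zero
  cond0 <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), 0, 1)
  expect_true(all(angular_displacement(cond0, tt) == 0))
})

test_that("motion map reduces to identity and preserves in-plane norms", {
  cond1 <- test_condition(sample_geometry(3e-3, 10e-3, 0), 0, 1)
  X <- c(1e-3, 2e-3, 1.5e-3)
  expect_equal(motion_map(X, cond1, 0.3), X)
  cond <- quick_cond(cs = 0.1, shear = 0.5)
  # rotation preserves the (widened) in-plane norm
  x <- motion_map(X, cond, 0.17)
  expect_equal(sqrt(sum(x[1:2]^2)),
               sqrt(sum(X[1:2]^2)) / sqrt(cond$geometry$lam))
  expect_equal(abs(x[3]), cond$geometry$lam * X[3])
  # at X3 = H the rotation angle equals the top-plate angle
  H <- cond$geometry$H
  xt <- motion_map(c(1e-3, 0, H), cond, 0.17)
  expect_equal(atan2(xt[2], xt[1]), angular_displacement(cond, 0.17))
})

test_that("deformation gradient is isochoric and matches the motion-map Jacobian", {
  set.seed(11)
  for (rep in 1:8) {
    cs <- runif(1, 0, 0.25)
    cond <- quick_cond(cs = cs, shear = runif(1, 0, 0.5),
                       freq = sample(c(0.5, 1, 2), 1))
    g <- cond$geometry
    pt <- material_point(runif(1, 0, g$r), runif(1, -pi, pi),
                         runif(1, 0, g$H))
    t0 <- runif(1, 0, 2)
    F <- deformation_gradient(pt, cond, t0)
    expect_lt(abs(det(F) - 1), 1e-12)
    # finite-difference Jacobian of the motion map (referential coords)
    Rx <- pt$r_x * sqrt(g$lam)
    X <- c(Rx * cos(pt$theta0), Rx * sin(pt$theta0), pt$X3)
    h <- 1e-7
    Jfd <- vapply(1:3, function(j) {
      e <- numeric(3); e[j] <- h
      (motion_map(X + e, cond, t0) - motion_map(X - e, cond, t0)) / (2 * h)
    }, numeric(3))
    expect_lt(max(abs(F - Jfd)) / max(abs(F)), 1e-6)
  }
  # points outside the sample are rejected
  cond <- quick_cond()
  expect_error(
    deformation_gradient(material_point(2 * cond$geometry$r, 0, 1e-3), cond, 0),
    "outside")
})

test_that("top-surface gradient uses the plate angle", {
  cond <- quick_cond(cs = 0.1, shear = 0.5)
  g <- cond$geometry
  F <- deformation_gradient(material_point(g$r / 2, 0, g$H), cond, 0.13)
  psi <- angular_displacement(cond, 0.13)
  expect_equal(F[1, 1], cos(psi) / sqrt(g$lam))
  expect_equal(F[2, 3], psi / g$H * (g$r / 2) * cos(psi))
})

test_that("tensor invariants give trace and double contraction", {
  expect_equal(tensor_invariants(diag(3)), c(I = 3, II = 3))
  expect_equal(tensor_invariants(diag(c(2, 3, 4))), c(I = 9, II = 29))
  # simple-shear C with gamma = 0.5: II_C = 3 + 4 g^2 + g^4
  Fss <- matrix(c(1, 0, 0, 0.5, 1, 0, 0, 0, 1), 3, 3)
  C <- crossprod(Fss)
  expect_equal(unname(tensor_invariants(C)["II"]), 3 + 4 * 0.25 + 0.5^4)
  expect_error(tensor_invariants(matrix(1, 2, 3)), "square")
})

test_that("spectral decomposition reconstructs C and handles degeneracy", {
  sp <- spectral_decomposition(diag(3))
  expect_equal(sp$stretches, rep(1, 3))
  sp2 <- spectral_decomposition(diag(c(4, 1, 1)))
  expect_equal(sp2$stretches, c(2, 1, 1))
  expect_equal(abs(sp2$vectors[, 1]), c(1, 0, 0))
  set.seed(5)
  for (rep in 1:5) {
    C <- random_spd()
    sp <- spectral_decomposition(C)
    rec <- sp$vectors %*% (sp$stretches^2 * t(sp$vectors))
    expect_lt(max(abs(rec - C)), 1e-12 * max(abs(C)))
  }
  expect_error(spectral_decomposition(diag(c(1, -1, 1))), "positive definite")
  expect_error(spectral_decomposition(matrix(1:9, 3, 3) * 1.0), "symmetric")
})

test_that("spectral functions are basis-invariant in degenerate eigenspaces", {
  # at gamma = 0 the two in-plane stretches coincide; the Ogden kernel must
  # be invariant to rotations within that plane
  cond <- quick_cond(cs = 0.15, shear = 0)
  g <- cond$geometry
  st <- deformation_state(
    deformation_gradient(material_point(g$r / 2, 0, g$H), cond, 0.2))
  S <- pk2_ogden(st, 3.7)
  th <- 0.83
  Q <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(t(Q) %*% S %*% Q, S, tolerance = 1e-12)
})

test_that("deformation state exposes consistent measures", {
  set.seed(7)
  F <- random_isochoric_F()
  st <- deformation_state(F)
  expect_equal(st$J, 1, tolerance = 1e-12)
  expect_equal(st$C, crossprod(F))
  expect_equal(st$B, tcrossprod(F))
  expect_equal(det(st$C), st$J^2, tolerance = 1e-10)
  expect_equal(st$C_iso, st$C)  # J = 1
  expect_error(deformation_state(-diag(3)), "det")
})
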