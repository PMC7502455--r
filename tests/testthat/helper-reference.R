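# Shared fixtures and independent oracles, built in code at test time.

# A quick test condition (small grids keep the suite fast).
quick_cond <- function(cs = 0.1, shear = 0.25, freq = 1, Tp = 64,
                       burnin = 2, record = 1, H = 3e-3, R = 10e-3) {
  test_condition(sample_geometry(H, R, cs), shear, freq,
                 points_per_period = Tp, n_burnin = burnin, n_record = record)
}

random_spd <- function(scale = 1) {
  M <- matrix(rnorm(9), 3, 3)
  S <- crossprod(M) + diag(3) * 0.5
  S * scale
}

# Random isochoric deformation gradient (det = 1).
random_isochoric_F <- function() {
  F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
  while (det(F) <= 0.1) F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
  F / det(F)^(1 / 3)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# Central-difference PK2 from a strain-energy function W(C):
# S_ij = 2 dW/dC_ij, treating all nine components as independent.
fd_pk2 <- function(W, C, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    E <- matrix(0, 3, 3); E[i, j] <- h
    S[i, j] <- (W(C + E) - W(C - E)) / h
  }
  S
}

# Independent slow-route torque simulator: full 3x3 tensors at every radial
# quadrature node and time step, using only the elementary exported
# operations.  Cross-checks the vectorised component path in simulate_test.
reference_simulate <- function(params, cond) {
  g <- cond$geometry
  mesh <- radial_mesh(g$r)
  tg <- condition_times(cond)
  n <- tg$n
  tau <- matrix(0, n, 2)
  for (q in seq_along(mesh$rho)) {
    pt <- material_point(mesh$rho[q], 0, g$H)
    Sv <- matrix(0, n, 9)
    Se <- matrix(0, n, 9)
    Fs <- vector("list", n)
    for (k in seq_len(n)) {
      F <- deformation_gradient(pt, cond, tg$t[k])
      Fs[[k]] <- F
      st <- deformation_state(F)
      Sv[k, ] <- as.numeric(viscoelastic_kernel(params$model, st, params$b))
      Ek <- elastic_kernel(params$model, st, params$b)
      if (!is.null(Ek)) Se[k, ] <- as.numeric(Ek)
    }
    D <- caputo_derivative(Sv, params$alpha, tg$dt)
    for (k in seq_len(n)) {
      Dk <- matrix(D[k, ], 3, 3)
      if (params$model == "vexp") Dk <- dev_operator(Dk, crossprod(Fs[[k]]))
      sv <- cauchy_from_pk2(Fs[[k]], Dk)
      se <- cauchy_from_pk2(Fs[[k]], matrix(Se[k, ], 3, 3))
      psi_k <- angular_displacement(cond, tg$t[k])
      pos <- mesh$rho[q] * c(cos(psi_k), sin(psi_k))
      tau[k, 1] <- tau[k, 1] + mesh$w_area[q] * torque_integrand(se, pos)
      tau[k, 2] <- tau[k, 2] + mesh$w_area[q] * torque_integrand(sv, pos)
    }
  }
  list(tau_e = tau[tg$recorded, 1], tau_v = tau[tg$recorded, 2])
}
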