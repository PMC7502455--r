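# Fast kernel-component evaluation for the axisymmetric torsion field.
#
# On the top surface, at a material point of deformed radius rho (referential
# azimuth 0), the right Cauchy-Green tensor has the closed form
#   C11 = C22 = 1/lam, C12 = C13 = 0,
#   C23 = g / sqrt(lam), C33 = g^2 + lam^2,   with g(t) = psi(t) * rho / H.
# Every isotropic PK2 kernel A(C) inherits this block structure (A13 = 0 at
# azimuth 0; at azimuth theta0 the 13/23 pair just rotates), and the torque
# surface density reduces to
#   rho * sigma_theta_z = rho * lam * (A23 / sqrt(lam) + g * A33),
# so only the A23 and A33 components are ever needed.  `g` is an
# (n_times x n_nodes) matrix; vectors of the same shape are returned.
.kernel_components <- function(model, b, lam, g) {
  sl <- sqrt(lam)
  C23 <- g / sl
  C33 <- g^2 + lam^2
  out <- list(e = NULL, v = NULL)
  if (model == "vmr") {
    I_C <- 2 / lam + C33
    II_C <- 2 / lam^2 + 2 * g^2 / lam + C33^2
    iC23 <- -g / (lam * sl)          # (C^-1)_23
    iC33 <- 1 / lam^2                # (C^-1)_33
    out$v <- list(a23 = -I_C / 3 * iC23,
                  a33 = 1 - I_C / 3 * iC33)
    out$e <- list(a23 = (II_C - 3) * (C23 - II_C / 3 * iC23),
                  a33 = (II_C - 3) * (C33 - II_C / 3 * iC33))
  } else if (model == "vexp") {
    II_C <- 2 / lam^2 + 2 * g^2 / lam + C33^2
    E <- exp(b * (II_C - 3))
    out$v <- list(a23 = E * C23, a33 = E * C33)
  } else if (model == "vog") {
    # spectral function mu^((b-1)/2) of the in-plane/axial 2x2 block
    # [[1/lam, C23], [C23, C33]] (determinant lam), via the basis-free
    # divided-difference form f(M) = f(mu2) I + slope (M - mu2 I).
    tr <- 1 / lam + C33
    disc <- sqrt(pmax(tr^2 - 4 * lam, 0))
    mu1 <- (tr + disc) / 2
    mu2 <- (tr - disc) / 2
    p <- (b - 1) / 2
    f1 <- mu1^p
    f2 <- mu2^p
    slope <- ifelse(disc > 1e-12 * tr,
                    (f1 - f2) / pmax(disc, .Machine$double.xmin),
                    p * ((mu1 + mu2) / 2)^(p - 1))
    out$v <- list(a23 = slope * C23, a33 = f2 + slope * (C33 - mu2))
  } else {
    abort(sprintf("unknown model '%s'; available models are 'vmr', 'vog', 'vexp'", model))
  }
  out
}

# Precompute, for one test condition and one nonlinear power b, everything the
# torque assembly needs that does not depend on alpha: the radially weighted
# kernel sums P(t) = sum_k u1_k a23_k(t) and Q(t) = sum_k u2_k a33_k(t) with
# u1 = w_area * rho, u2 = w_area * rho^2 (elastic and viscoelastic), plus the
# imposed angle psi(t).  The fractional derivative acts linearly on the time
# axis, so it commutes with these spatial sums.
.torque_histories <- function(model, b, cond, mesh = NULL) {
  model <- tolower(model)
  g <- cond$geometry
  mesh <- mesh %||% radial_mesh(g$r)
  tg <- condition_times(cond)
  psi <- angular_displacement(cond, tg$t)
  G <- outer(psi, mesh$rho / g$H)            # n_times x n_nodes
  comp <- .kernel_components(model, b, g$lam, G)
  u1 <- mesh$w_area * mesh$rho
  u2 <- mesh$w_area * mesh$rho^2
  hist <- list(model = model, lam = g$lam, H = g$H, psi = psi,
               t = tg$t, dt = tg$dt, recorded = tg$recorded,
               Pv = drop(comp$v$a23 %*% u1), Qv = drop(comp$v$a33 %*% u2))
  if (!is.null(comp$e)) {
    hist$Pe <- drop(comp$e$a23 %*% u1)
    hist$Qe <- drop(comp$e$a33 %*% u2)
  }
  hist
}

# Unit-parameter torque components (per Pa of C_lin / delta) for one alpha,
# over the full simulated grid.  tau_e is NULL for models without an elastic
# term.  The deviatoric projection of the vEXP model is omitted here because
# its correction term maps to a hydrostatic Cauchy stress (F C^-1 F^T = I at
# J = 1), which carries no torque.
.torque_components <- function(hist, alpha) {
  D <- caputo_derivative(cbind(hist$Pv, hist$Qv), alpha, hist$dt)
  sl <- sqrt(hist$lam)
  out <- list(tau_v = sl * D[, 1] + hist$lam / hist$H * hist$psi * D[, 2])
  if (!is.null(hist$Pe)) {
    out$tau_e <- sl * hist$Pe + hist$lam / hist$H * hist$psi * hist$Qe
  }
  out
}

#' Simulate one large-amplitude oscillatory shear test
#'
#' Runs the forward model for one loading condition: builds the
#' compression-torsion deformation history over the burn-in plus recorded
#' cycles, evaluates the model's elastic and viscoelastic PK2 kernels at
#' every integration point of the top surface, applies the Caputo fractional
#' derivative to the full kernel history (so memory effects cross the
#' recording boundary), maps to Cauchy stress and integrates the axial
#' torque.  Only the recorded window is returned.
#'
#' The returned components `tau_e` and `tau_v` are *unit-parameter* torques
#' (the torque per Pa of `C_lin` and `delta` respectively); the combined
#' torque is `tau = C_lin * tau_e + delta * tau_v`.  Models without an
#' elastic term (`"vog"`, `"vexp"`) report `tau_e = 0`.
#'
#' @param params A [material_parameters()].
#' @param cond A [test_condition()].
#' @param mesh Optional [radial_mesh()] or [disc_mesh()]; defaults to a
#'   radial Gauss-Legendre rule of order 16 on the deformed disc, which
#'   matches a fine triangulation to near machine precision at a fraction of
#'   the cost.
#' @return A tibble of class `torque_trace` with columns `time` (s), `angle`
#'   (imposed top-plate angle, rad), `tau_e`, `tau_v` (unit-parameter
#'   components, N m/Pa) and `tau` (N m).  The condition and parameters are
#'   attached as attributes `condition` and `parameters`.
#' @examples
#' cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), 0.25, 1,
#'                        points_per_period = 64, n_burnin = 2, n_record = 1)
#' pars <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
#' tr <- simulate_test(pars, cond)
#' range(tr$tau)
#' @export
simulate_test <- function(params, cond, mesh = NULL) {
  stopifnot(inherits(params, "material_parameters"),
            inherits(cond, "test_condition"))
  hist <- .torque_histories(params$model, params$b, cond, mesh)
  comp <- .torque_components(hist, params$alpha)
  rec <- hist$recorded
  tau_e <- if (is.null(comp$tau_e)) rep(0, sum(rec)) else comp$tau_e[rec]
  tau_v <- comp$tau_v[rec]
  C_lin <- if (is.na(params$C_lin)) 0 else params$C_lin
  out <- tibble::tibble(
    time = hist$t[rec], angle = hist$psi[rec],
    tau_e = tau_e, tau_v = tau_v,
    tau = C_lin * tau_e + params$delta * tau_v
  )
  class(out) <- c("torque_trace", class(out))
  attr(out, "condition") <- cond
  attr(out, "parameters") <- params
  out
}

#' Harmonic content of a periodic signal
#'
#' Least-squares projection of `y` onto the first `n_harmonics` harmonics of
#' the fundamental frequency, written as
#' \eqn{y(t) \approx c_0 + \sum_h A_h \sin(2\pi h f t + \phi_h)}.  Intended
#' for steady-state (post-burn-in) windows spanning an integer number of
#' periods.
#'
#' @param time Sample times (s).
#' @param y Signal samples.
#' @param freq Fundamental frequency (Hz).
#' @param n_harmonics Number of harmonics to extract (default 5).
#' @return A tibble with columns `harmonic`, `amplitude` and `phase` (rad,
#'   relative to \eqn{\sin(2\pi h f t)}).
#' @export
fourier_harmonics <- function(time, y, freq, n_harmonics = 5) {
  stopifnot(length(time) == length(y), length(time) > 2 * n_harmonics + 1)
  X <- do.call(cbind, lapply(seq_len(n_harmonics), function(h) {
    cbind(sin(2 * pi * h * freq * time), cos(2 * pi * h * freq * time))
  }))
  fit <- stats::lsfit(X, y, intercept = TRUE)
  cf <- unname(fit$coefficients[-1])
  s <- cf[seq(1, length(cf), by = 2)]
  cc <- cf[seq(2, length(cf), by = 2)]
  tibble::tibble(harmonic = seq_len(n_harmonics),
                 amplitude = sqrt(s^2 + cc^2),
                 phase = atan2(cc, s))
}

#' Total harmonic distortion of a periodic signal
#'
#' Ratio of the combined amplitude of harmonics 2..`n_harmonics` to the
#' fundamental amplitude.  In the linear viscoelastic regime the torque
#' response to a sinusoidal shear is itself sinusoidal (distortion near 0);
#' the nonlinear powers of the Ogden and exponential models raise it with
#' increasing shear amplitude.
#'
#' @inheritParams fourier_harmonics
#' @return A single number (fractional distortion).
#' @export
harmonic_distortion <- function(time, y, freq, n_harmonics = 7) {
  h <- fourier_harmonics(time, y, freq, n_harmonics)
  sqrt(sum(h$amplitude[-1]^2)) / h$amplitude[1]
}
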