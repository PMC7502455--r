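#' Material parameters of a fractional viscoelastic model
#'
#' Three constitutive families are supported, each built from second
#' Piola-Kirchhoff (PK2) kernels and a Caputo fractional derivative
#' \eqn{D_t^\alpha} of the viscoelastic kernel's time history:
#'
#' * `"vmr"` — modified Mooney-Rivlin:
#'   \eqn{S = C\,S_e^2 + \delta\,D_t^\alpha(S_e^1) + S_p}, where
#'   \eqn{S_e^1} is a neo-Hookean (linear-in-shear) kernel and
#'   \eqn{S_e^2} a quadratic second-invariant kernel.
#' * `"vog"` — viscoelastic Ogden:
#'   \eqn{S = \delta\,D_t^\alpha(S_e^b) + S_p} with the principal-stretch
#'   kernel \eqn{S_e^b = \sum_i \lambda_i^{b-1} v_i \otimes v_i}.
#' * `"vexp"` — viscoelastic Fung exponential:
#'   \eqn{S = \delta\,\mathrm{Dev}[D_t^\alpha(S_e^b)] + S_p} with
#'   \eqn{S_e^b = e^{b(II_C - 3)} C}; the deviatoric projection uses the
#'   current-time \eqn{C} and is applied after the fractional derivative so
#'   that deviatoric and hydrostatic parts stay separated.
#'
#' `C_lin` and `delta` (Pa) scale the model components linearly and are
#' constrained to the nonnegative orthant; `alpha` (the fractional order)
#' and `b` (the nonlinear power) shape the torque response nonlinearly.
#'
#' @param model One of `"vmr"`, `"vog"`, `"vexp"` (case-insensitive).
#' @param delta Viscoelastic scale \eqn{\delta \ge 0} in Pa.
#' @param alpha Fractional order in \[0, 1\].
#' @param C_lin Elastic scale \eqn{C \ge 0} in Pa (`"vmr"` only).
#' @param b Nonlinear power (required for `"vog"` and `"vexp"`).
#' @return An object of class `material_parameters`.
#' @examples
#' material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
#' @export
material_parameters <- function(model, delta, alpha, C_lin = NULL, b = NULL) {
  model <- tolower(as.character(model))
  if (!model %in% c("vmr", "vog", "vexp")) {
    abort(sprintf("unknown model '%s'; available models are 'vmr', 'vog', 'vexp'", model))
  }
  stopifnot(is.numeric(delta), length(delta) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (delta < 0) abort("`delta` must be nonnegative (Pa).")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (model == "vmr") {
    C_lin <- C_lin %||% 0
    stopifnot(is.numeric(C_lin), length(C_lin) == 1L)
    if (C_lin < 0) abort("`C_lin` must be nonnegative (Pa).")
    b <- NA_real_
  } else {
    if (is.null(b)) abort(sprintf("model '%s' requires the nonlinear power `b`.", model))
    stopifnot(is.numeric(b), length(b) == 1L)
    if (b <= 0) abort("`b` must be positive.")
    C_lin <- NA_real_
  }
  structure(list(model = model, C_lin = C_lin, delta = delta,
                 alpha = alpha, b = b),
            class = "material_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.material_parameters <- function(x, ...) {
  cat(sprintf("<material_parameters> model %s: delta = %.4g Pa, alpha = %.3g",
              x$model, x$delta, x$alpha))
  if (x$model == "vmr") cat(sprintf(", C = %.4g Pa", x$C_lin))
  if (!is.na(x$b)) cat(sprintf(", b = %.3g", x$b))
  cat("\n")
  invisible(x)
}

#' Lagrangian deviatoric operator
#'
#' \eqn{\mathrm{Dev}[A] = A - \frac{A : C}{3} C^{-1}}, the projection that
#' makes a referential tensor orthogonal to `C` under the double
#' contraction: \eqn{\mathrm{Dev}[A] : C = 0}.
#'
#' @param A Symmetric 3x3 matrix.
#' @param C Symmetric invertible 3x3 matrix (right Cauchy-Green tensor).
#' @return A 3x3 matrix.
#' @export
dev_operator <- function(A, C) {
  stopifnot(is.matrix(A), all(dim(A) == c(3L, 3L)),
            is.matrix(C), all(dim(C) == c(3L, 3L)))
  dC <- det(C)
  if (!is.finite(dC) || abs(dC) < .Machine$double.eps * 100) {
    abort("`C` must be invertible.")
  }
  A - sum(A * C) / 3 * solve(C)
}

#' Neo-Hookean PK2 kernel of the modified Mooney-Rivlin model
#'
#' \eqn{S_e^1 = J^{-2/3} (I - \frac{I_C}{3} C^{-1})}, the PK2 derivative of
#' the isochoric neo-Hookean energy \eqn{W_1 = (I_{\hat C} - 3)/2}.  Linear
#' in shear; this is the kernel whose history is fractionally differentiated
#' in the `"vmr"` model.
#'
#' @param state A [deformation_state()].
#' @return A symmetric 3x3 matrix.
#' @export
pk2_mr1 <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  C <- state$C
  state$J^(-2 / 3) * (diag(3) - sum(diag(C)) / 3 * solve(C))
}

#' Quadratic second-invariant PK2 kernel of the modified Mooney-Rivlin model
#'
#' \eqn{S_e^2 = J^{-4/3} (II_{\hat C} - 3) (C - \frac{II_C}{3} C^{-1})}, the
#' PK2 derivative of \eqn{W_2 = (II_{\hat C} - 3)^2 / 8}.  Quadratic in the
#' second invariant, so it switches on a nonlinear elastic response at large
#' shear.
#'
#' @inheritParams pk2_mr1
#' @return A symmetric 3x3 matrix.
#' @export
pk2_mr2 <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  C <- state$C
  II_C <- sum(C * C)
  II_hat <- state$J^(-4 / 3) * II_C
  state$J^(-4 / 3) * (II_hat - 3) * (C - II_C / 3 * solve(C))
}

#' Ogden-type principal-stretch PK2 kernel
#'
#' \eqn{S_e^b = \sum_{i=1}^3 \lambda_i^{b-1} v_i \otimes v_i}, where
#' \eqn{\lambda_i} are the principal stretches (square roots of the
#' eigenvalues of `C`) and \eqn{v_i} the eigenvectors of `C`.  Implemented
#' exactly in this printed form, which is the spectral function
#' \eqn{C^{(b-1)/2}}; note it is not the literal derivative of the one-term
#' Ogden energy \eqn{W = (\sum_i \lambda_i^b - 3)/(2b)} (that derivative
#' would carry weights \eqn{\lambda_i^{b-2}}).  Fidelity to the published
#' stress form is preferred; see the methods vignette.
#'
#' @inheritParams pk2_mr1
#' @param b Nonlinear power.
#' @return A symmetric 3x3 matrix.
#' @export
pk2_ogden <- function(state, b) {
  stopifnot(inherits(state, "deformation_state"),
            is.numeric(b), length(b) == 1L)
  v <- state$vectors
  v %*% (state$stretches^(b - 1) * t(v))
}

#' Fung-exponential PK2 kernel
#'
#' \eqn{S_e^b = e^{b (II_C - 3)} C}, the PK2 derivative of the isotropic
#' exponential energy \eqn{W = (e^{b(II_C - 3)} - 1)/(4b)}.  The exponent
#' uses the full (non-isochoric) `C` as printed; under the isochoric torsion
#' protocol `J = 1` so the distinction is empty.
#'
#' @inheritParams pk2_ogden
#' @return A symmetric 3x3 matrix.
#' @export
pk2_exp <- function(state, b) {
  stopifnot(inherits(state, "deformation_state"),
            is.numeric(b), length(b) == 1L, b > 0)
  exp(b * (sum(state$C * state$C) - 3)) * state$C
}

#' Elastic PK2 kernel of a model
#'
#' The purely elastic kernel scaled by `C_lin`: \eqn{S_e^2} for `"vmr"`;
#' the Ogden and exponential models have no separate elastic term (their
#' single kernel is fractionally differentiated), so `NULL` is returned.
#'
#' @param model Model name (`"vmr"`, `"vog"`, `"vexp"`).
#' @inheritParams pk2_ogden
#' @return A 3x3 matrix, or `NULL` when the model has no elastic part.
#' @export
elastic_kernel <- function(model, state, b = NA_real_) {
  model <- tolower(model)
  switch(model,
         vmr = pk2_mr2(state),
         vog = NULL,
         vexp = NULL,
         abort(sprintf("unknown model '%s'; available models are 'vmr', 'vog', 'vexp'", model)))
}

#' Viscoelastic PK2 kernel of a model (pre-fractional-derivative)
#'
#' Returns the tensor whose time history is fed to the Caputo derivative:
#' \eqn{S_e^1} for `"vmr"`, the Ogden kernel for `"vog"`, the exponential
#' kernel for `"vexp"`.  For `"vexp"` the deviatoric projection of the total
#' stress is applied *after* the fractional derivative, using the
#' current-time `C` — see [dev_operator()]; it is not part of this kernel.
#'
#' @inheritParams elastic_kernel
#' @return A symmetric 3x3 matrix.
#' @export
viscoelastic_kernel <- function(model, state, b = NA_real_) {
  model <- tolower(model)
  switch(model,
         vmr = pk2_mr1(state),
         vog = pk2_ogden(state, b),
         vexp = pk2_exp(state, b),
         abort(sprintf("unknown model '%s'; available models are 'vmr', 'vog', 'vexp'", model)))
}

#' Hydrostatic pressure recovered from the traction-free wall
#'
#' On the lateral wall of the sample the traction vanishes, so the normal
#' component of \eqn{\sigma = F (S_e + D_t^\alpha S_v) F^T + J P I} must be
#' zero.  Given the combined non-hydrostatic PK2 tensor
#' `S_ev` \eqn{= S_e + D_t^\alpha S_v} at a wall point, the pressure follows
#' as \eqn{P = - n^T F S_{ev} F^T n / (J \, |n|^2)}.  The pressure never
#' contributes to the measured torque (a hydrostatic Cauchy stress has no
#' 13/23 moment), so this is exposed for completeness, not used in fitting.
#'
#' @param F Deformation gradient at the wall point.
#' @param S_ev Combined elastic plus fractionally differentiated
#'   viscoelastic PK2 tensor at that point.
#' @param normal Outward wall normal (any nonzero length).
#' @return Hydrostatic pressure `P` in Pa.
#' @export
recover_wall_pressure <- function(F, S_ev, normal) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)),
            is.matrix(S_ev), all(dim(S_ev) == c(3L, 3L)),
            is.numeric(normal), length(normal) == 3L)
  nn <- sum(normal^2)
  if (nn == 0) abort("`normal` must have nonzero length.")
  J <- det(F)
  -as.numeric(t(normal) %*% F %*% S_ev %*% t(F) %*% normal) / (J * nn)
}
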