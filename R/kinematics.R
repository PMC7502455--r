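#' Top-plate angular displacement
#'
#' The imposed rotation of the top plate at time `t`,
#' \eqn{\psi(t) = \sin(2\pi f t) \, h \gamma / r}, where `h` and `r` are the
#' deformed height and radius.  Its maximum over time is \eqn{h\gamma/r}.
#'
#' @param cond A [test_condition()].
#' @param t Time(s) in seconds (vectorised).
#' @return Angular displacement(s) in radians.
#' @examples
#' cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), 0.5, 1)
#' angular_displacement(cond, 0.25)
#' @export
angular_displacement <- function(cond, t) {
  stopifnot(inherits(cond, "test_condition"), is.numeric(t))
  g <- cond$geometry
  sin(2 * pi * cond$freq * t) * g$h * cond$gamma / g$r
}

#' Compression-torsion motion map
#'
#' Maps a referential point \eqn{X = (X_1, X_2, X_3)} of the undeformed
#' cylinder to its spatial position at time `t` under ideal compression
#' (axial stretch \eqn{\lambda}, in-plane widening \eqn{1/\sqrt{\lambda}})
#' combined with a torsion whose angle varies linearly along the axis,
#' \eqn{\Psi(t, X_3) = \psi(t) X_3 / H}.
#'
#' @param X Numeric length-3 vector of referential coordinates (m).
#' @inheritParams angular_displacement
#' @return Numeric length-3 spatial position (m).
#' @export
motion_map <- function(X, cond, t) {
  stopifnot(is.numeric(X), length(X) == 3L,
            inherits(cond, "test_condition"),
            is.numeric(t), length(t) == 1L)
  g <- cond$geometry
  Psi <- angular_displacement(cond, t) * X[3] / g$H
  sl <- sqrt(g$lam)
  c(X[1] / sl * cos(Psi) - X[2] / sl * sin(Psi),
    X[1] / sl * sin(Psi) + X[2] / sl * cos(Psi),
    g$lam * X[3])
}

#' Deformation gradient of the compression-torsion field
#'
#' Returns the exact 3x3 deformation gradient `F` of the combined
#' compression-torsion motion at a material point, with
#' \eqn{\theta(t) = \theta_0 + \Psi(t, X_3)} and `r_x` the deformed radial
#' position.  On the top surface (`X3 = H`) the torsion angle
#' \eqn{\Psi(t, X_3)} reduces to the plate angle \eqn{\psi(t)}.  The motion is
#' isochoric: `det(F) = 1` to machine precision for every admissible input.
#'
#' @param point A [material_point()].
#' @inheritParams angular_displacement
#' @return A 3x3 matrix.
#' @export
deformation_gradient <- function(point, cond, t) {
  stopifnot(inherits(point, "material_point"),
            inherits(cond, "test_condition"),
            is.numeric(t), length(t) == 1L)
  g <- cond$geometry
  if (point$r_x > g$r * (1 + 1e-12)) {
    abort(sprintf("material point r_x = %.4g m lies outside the deformed sample radius r = %.4g m",
                  point$r_x, g$r))
  }
  psi <- angular_displacement(cond, t)
  Psi <- psi * point$X3 / g$H
  theta <- point$theta0 + Psi
  sl <- sqrt(g$lam)
  shear <- psi / g$H * point$r_x
  matrix(c(
    cos(Psi) / sl, -sin(Psi) / sl, -shear * sin(theta),
    sin(Psi) / sl,  cos(Psi) / sl,  shear * cos(theta),
    0,              0,              g$lam
  ), nrow = 3, byrow = TRUE)
}

#' Strain state derived from a deformation gradient
#'
#' Computes the standard finite-strain measures at one material point and
#' time: `J = det(F)`, the right and left Cauchy-Green tensors
#' `C = t(F) %*% F` and `B = F %*% t(F)`, their isochoric forms
#' \eqn{\hat C = J^{-2/3} C}, \eqn{\hat B = J^{-2/3} B}, and the spectral
#' decomposition of `C` (principal stretches \eqn{\lambda_i} = square roots
#' of the eigenvalues of `C`, with orthonormal eigenvectors).
#'
#' @param F A 3x3 deformation gradient with positive determinant.
#' @return An object of class `deformation_state`: list with `F`, `J`, `C`,
#'   `B`, `C_iso`, `B_iso`, `stretches`, `vectors` (eigenvectors as columns,
#'   matching `stretches`).
#' @export
deformation_state <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)), is.numeric(F))
  J <- det(F)
  if (!is.finite(J) || J <= 0) abort("deformation gradient must have det(F) > 0")
  C <- crossprod(F)
  B <- tcrossprod(F)
  sp <- spectral_decomposition(C)
  structure(
    list(F = F, J = J, C = C, B = B,
         C_iso = J^(-2 / 3) * C, B_iso = J^(-2 / 3) * B,
         stretches = sp$stretches, vectors = sp$vectors),
    class = "deformation_state"
  )
}

#' First and second tensor invariants
#'
#' The first invariant is the trace, \eqn{I_A = A : I}; the second is the
#' Frobenius double contraction, \eqn{II_A = A : A}.
#'
#' @param A A square numeric matrix.
#' @return Named numeric vector `c(I = trace, II = A:A)`.
#' @examples
#' tensor_invariants(diag(3))  # c(I = 3, II = 3)
#' @export
tensor_invariants <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A)) {
    abort("`A` must be a square numeric matrix.")
  }
  c(I = sum(diag(A)), II = sum(A * A))
}

#' Spectral decomposition of a right Cauchy-Green tensor
#'
#' Returns the principal stretches \eqn{\lambda_i = \sqrt{\mu_i}} (where
#' \eqn{\mu_i} are the eigenvalues of `C`) and the corresponding orthonormal
#' eigenvectors.  Eigenvector signs and the basis within degenerate
#' eigenspaces are not unique; downstream quantities are spectral functions
#' \eqn{\sum_i f(\lambda_i) v_i \otimes v_i}, which are well defined
#' regardless.
#'
#' @param C A symmetric positive-definite 3x3 matrix.
#' @return List with `stretches` (decreasing) and `vectors` (columns).
#' @export
spectral_decomposition <- function(C) {
  stopifnot(is.matrix(C), all(dim(C) == c(3L, 3L)), is.numeric(C))
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    abort("`C` must be symmetric.")
  }
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) abort("`C` must be positive definite.")
  list(stretches = sqrt(e$values), vectors = e$vectors)
}
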