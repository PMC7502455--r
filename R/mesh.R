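#' Radial quadrature over the deformed top disc
#'
#' Because the compression-torsion stress field is axisymmetric, the torque
#' integral over the top disc of radius `r` collapses to a one-dimensional
#' radial integral, \eqn{\tau_3 = 2\pi \int_0^r \rho^2 \sigma_{\theta z}(\rho)
#' \, d\rho}.  This mesh carries Gauss-Legendre nodes \eqn{\rho_q} on
#' \eqn{[0, r]} with area weights \eqn{2\pi \rho_q w_q}, which integrate the
#' disc area \eqn{\pi r^2} exactly.
#'
#' @param r Deformed disc radius (m), or a [sample_geometry()].
#' @param order Gauss-Legendre order (default 16).
#' @return A `surface_mesh` object with fields `mode = "radial"`, `rho`
#'   (node radii), `w_area` (area weights), `theta0` (zeros) and `r`.
#' @export
radial_mesh <- function(r, order = 16) {
  if (inherits(r, "sample_geometry")) r <- r$r
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, order >= 2)
  gl <- pracma::gaussLegendre(order, 0, r)
  structure(
    list(mode = "radial", rho = gl$x, w_area = 2 * pi * gl$x * gl$w,
         theta0 = rep(0, length(gl$x)), r = r, order = as.integer(order)),
    class = "surface_mesh"
  )
}

#' Triangulated mesh of the deformed top disc
#'
#' A structured triangulation built from `sectors` angular sectors and
#' `rings` radial rings: a central fan of `sectors` triangles plus
#' `2 * sectors` triangles per outer ring, i.e.
#' `sectors * (2 * rings - 1)` elements (the default 45 x 9 layout gives
#' 765 elements).  Fields are evaluated at element centroids with flat
#' triangle areas as weights.  Node radii are inflated by the constant
#' factor \eqn{\sqrt{2\pi / (s \sin(2\pi/s))}} so that the flat-element
#' areas sum exactly to the disc area \eqn{\pi r^2} (a polygon inscribed in
#' the circle would underestimate it by \eqn{\sin(h)/h}, \eqn{h = 2\pi/s}).
#'
#' @inheritParams radial_mesh
#' @param sectors Angular subdivisions (default 45).
#' @param rings Radial subdivisions (default 9).
#' @return A `surface_mesh` with `mode = "triangulated"`, centroid
#'   coordinates `x1`, `x2`, centroid radii `rho`, azimuths `theta0` and
#'   element areas `w_area`.
#' @export
disc_mesh <- function(r, sectors = 45, rings = 9) {
  if (inherits(r, "sample_geometry")) r <- r$r
  stopifnot(is.numeric(r), length(r) == 1L, r > 0, sectors >= 3, rings >= 1)
  s <- as.integer(sectors); m <- as.integer(rings)
  scale <- sqrt(2 * pi / (s * sin(2 * pi / s)))
  ring_r <- scale * r * seq(0, m) / m
  ang <- function(k) 2 * pi * k / s
  node <- function(j, k) c(ring_r[j + 1L] * cos(ang(k)), ring_r[j + 1L] * sin(ang(k)))
  tri <- vector("list", s * (2L * m - 1L))
  idx <- 0L
  for (k in seq_len(s) - 1L) {      # central fan
    idx <- idx + 1L
    tri[[idx]] <- rbind(c(0, 0), node(1L, k), node(1L, k + 1L))
  }
  for (j in seq_len(m - 1L)) {      # annular rings j -> j + 1
    for (k in seq_len(s) - 1L) {
      a <- node(j, k); b <- node(j + 1L, k)
      cc <- node(j + 1L, k + 1L); d <- node(j, k + 1L)
      idx <- idx + 1L; tri[[idx]] <- rbind(a, b, cc)
      idx <- idx + 1L; tri[[idx]] <- rbind(a, cc, d)
    }
  }
  cent <- t(vapply(tri, colMeans, numeric(2)))
  area <- vapply(tri, function(v) {
    abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
        (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
  }, numeric(1))
  structure(
    list(mode = "triangulated", x1 = cent[, 1], x2 = cent[, 2],
         rho = sqrt(rowSums(cent^2)), theta0 = atan2(cent[, 2], cent[, 1]),
         w_area = area, r = r, n_elements = length(area)),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  if (x$mode == "radial") {
    cat(sprintf("<surface_mesh> radial Gauss-Legendre, order %d, r = %.4g m\n",
                x$order, x$r))
  } else {
    cat(sprintf("<surface_mesh> triangulated disc, %d elements, r = %.4g m\n",
                x$n_elements, x$r))
  }
  invisible(x)
}

#' Cauchy stress from a PK2 tensor
#'
#' \eqn{\sigma = \frac{1}{J} F S F^T}.  Symmetric whenever `S` is.
#'
#' @param F Deformation gradient (3x3).
#' @param S PK2 tensor (3x3).
#' @param J Determinant of `F`; computed from `F` if omitted.
#' @return A 3x3 matrix.
#' @export
cauchy_from_pk2 <- function(F, S, J = det(F)) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)),
            is.matrix(S), all(dim(S) == c(3L, 3L)), J > 0)
  F %*% S %*% t(F) / J
}

#' Axial torque integrand on the top disc
#'
#' The only nonzero torque component about the cylinder axis has surface
#' density \eqn{r_1 \sigma_{23} - r_2 \sigma_{13}}, where \eqn{(r_1, r_2)}
#' are the in-plane deformed coordinates of the evaluation point (the lever
#' arm).  A hydrostatic stress contributes nothing.
#'
#' @param sigma Cauchy stress (3x3) at the point.
#' @param position Numeric vector; first two entries are the in-plane
#'   deformed coordinates (m).
#' @return Scalar integrand value (Pa m).
#' @export
torque_integrand <- function(sigma, position) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3L, 3L)),
            is.numeric(position), length(position) >= 2L)
  position[1] * sigma[2, 3] - position[2] * sigma[1, 3]
}

#' Integrate the axial torque of a stress field over the top disc
#'
#' Evaluates `stress_fn(x1, x2)` (returning a 3x3 Cauchy stress) at every
#' mesh node and sums the torque integrand with the mesh area weights.  The
#' radial mode places its nodes on the \eqn{\theta = 0} ray and exploits
#' axisymmetry; the triangulated mode evaluates at element centroids.
#'
#' @param mesh A [radial_mesh()] or [disc_mesh()].
#' @param stress_fn Function of `(x1, x2)` returning a 3x3 matrix.
#' @return Torque \eqn{\tau_3} in N m.
#' @examples
#' # rigid torsion-like field sigma_13 = -x2, sigma_23 = x1 over r = 1:
#' f <- function(x1, x2) matrix(c(0, 0, -x2, 0, 0, x1, -x2, x1, 0), 3, 3)
#' integrate_torque(radial_mesh(1), f)  # pi/2
#' @export
integrate_torque <- function(mesh, stress_fn) {
  stopifnot(inherits(mesh, "surface_mesh"), is.function(stress_fn))
  if (length(mesh$rho) == 0L) abort("mesh has no nodes")
  x1 <- mesh$rho * cos(mesh$theta0)
  x2 <- mesh$rho * sin(mesh$theta0)
  vals <- vapply(seq_along(x1), function(i) {
    torque_integrand(stress_fn(x1[i], x2[i]), c(x1[i], x2[i]))
  }, numeric(1))
  sum(mesh$w_area * vals)
}
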