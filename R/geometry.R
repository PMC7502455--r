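#' Cylindrical sample geometry under compressive preload
#'
#' Describes a cylindrical tissue sample mounted between rheometer plates and
#' pre-compressed along its axis.  Ideal (homogeneous, volume-preserving)
#' compression is assumed: an axial stretch `lam = 1 - compression` reduces
#' the height to `h = lam * height` and widens the radius to
#' `r = radius / sqrt(lam)`, so that `h * r^2 = height * radius^2`.
#'
#' @param height Undeformed sample height \eqn{H} in metres.
#' @param radius Undeformed sample radius \eqn{R} in metres.
#' @param compression Compressive strain \eqn{CS \in [0, 1)} as a fraction
#'   (e.g. `0.10` for 10\%).
#'
#' @return An object of class `sample_geometry`: a list with fields `H`, `R`,
#'   `cs`, `lam` (axial stretch), `h` (deformed height) and `r` (deformed
#'   radius), all SI.
#' @examples
#' geo <- sample_geometry(height = 3e-3, radius = 10e-3, compression = 0.1)
#' geo$h * geo$r^2 - geo$H * geo$R^2  # volume conserved
#' @export
sample_geometry <- function(height, radius, compression = 0) {
  stopifnot(is.numeric(height), length(height) == 1L, height > 0,
            is.numeric(radius), length(radius) == 1L, radius > 0,
            is.numeric(compression), length(compression) == 1L)
  if (compression < 0 || compression >= 1) {
    abort("`compression` must be a fraction in [0, 1).")
  }
  lam <- 1 - compression
  structure(
    list(H = height, R = radius, cs = compression,
         lam = lam, h = lam * height, r = radius / sqrt(lam)),
    class = "sample_geometry"
  )
}

#' @export
print.sample_geometry <- function(x, ...) {
  cat(sprintf(
    "<sample_geometry> H = %.3g mm, R = %.3g mm, CS = %.3g%% (lam = %.4g)\n",
    1e3 * x$H, 1e3 * x$R, 100 * x$cs, x$lam))
  cat(sprintf("  deformed: h = %.3g mm, r = %.3g mm\n", 1e3 * x$h, 1e3 * x$r))
  invisible(x)
}

#' One loading cell of the oscillatory testing protocol
#'
#' Bundles the sample geometry with a single (compression, shear amplitude,
#' frequency) loading condition and the discrete sampling scheme used by the
#' forward simulator: `points_per_period` samples per oscillation period
#' (`dt = 1 / (freq * points_per_period)`), `n_burnin` preconditioning cycles
#' that are simulated but not recorded, and `n_record` recorded cycles.
#'
#' @param geometry A [sample_geometry()].
#' @param shear Shear-strain amplitude \eqn{\gamma \ge 0} as a fraction
#'   (top-plate rotational displacement over inter-plate gap).
#' @param freq Oscillation frequency in Hz.
#' @param points_per_period Number of time samples per period (default 200).
#' @param n_burnin Number of preconditioning cycles preceding the recording
#'   window (default 8).
#' @param n_record Number of recorded cycles (default 3).
#'
#' @return An object of class `test_condition`.
#' @examples
#' cond <- test_condition(sample_geometry(3e-3, 10e-3, 0.1), shear = 0.5, freq = 1)
#' cond$dt * cond$points_per_period * cond$freq  # exactly 1
#' @export
test_condition <- function(geometry, shear, freq, points_per_period = 200,
                           n_burnin = 8, n_record = 3) {
  stopifnot(inherits(geometry, "sample_geometry"),
            is.numeric(shear), length(shear) == 1L, shear >= 0,
            is.numeric(freq), length(freq) == 1L, freq > 0,
            points_per_period >= 4, n_burnin >= 0, n_record >= 1)
  structure(
    list(geometry = geometry, gamma = shear, freq = freq,
         points_per_period = as.integer(points_per_period),
         dt = 1 / (freq * points_per_period),
         n_burnin = as.integer(n_burnin), n_record = as.integer(n_record)),
    class = "test_condition"
  )
}

#' @export
print.test_condition <- function(x, ...) {
  cat(sprintf(
    "<test_condition> CS %.3g%%, shear %.3g%%, %g Hz (T = %d, burn-in %d + %d recorded cycles)\n",
    100 * x$geometry$cs, 100 * x$gamma, x$freq,
    x$points_per_period, x$n_burnin, x$n_record))
  invisible(x)
}

#' Simulation time grid of a test condition
#'
#' The grid starts at `t = 0`, the instant the compressed preloaded state is
#' reached (the compression ramp itself is not simulated), and spans the
#' burn-in plus recorded cycles at uniform spacing `dt`.  The recorded window
#' starts at the end of the burn-in, endpoint included.
#'
#' @param cond A [test_condition()].
#' @return A list with `t` (times, s), `dt`, `n` (number of samples) and
#'   `recorded` (logical index of the recording window).
#' @export
condition_times <- function(cond) {
  stopifnot(inherits(cond, "test_condition"))
  Tp <- cond$points_per_period
  n <- (cond$n_burnin + cond$n_record) * Tp + 1L
  k <- seq_len(n) - 1L
  list(t = k * cond$dt, dt = cond$dt, n = n,
       recorded = k >= cond$n_burnin * Tp)
}

#' A material point of the sample
#'
#' Points are parametrised by their *deformed* radial position `r_x` (the
#' radius at which they sit once the preload is applied), their referential
#' azimuth `theta0` and their referential axial coordinate `X3`.  The
#' referential radius is `r_x * sqrt(lam)`.
#'
#' @param r_x Deformed radial position in metres (`0 <= r_x <= r`).
#' @param theta0 Referential azimuth in radians.
#' @param X3 Referential axial coordinate in metres (`X3 = H` is the top
#'   surface, where the torque is measured).
#' @return An object of class `material_point`.
#' @export
material_point <- function(r_x, theta0 = 0, X3) {
  stopifnot(is.numeric(r_x), length(r_x) == 1L, r_x >= 0,
            is.numeric(theta0), length(theta0) == 1L,
            is.numeric(X3), length(X3) == 1L, X3 >= 0)
  structure(list(r_x = r_x, theta0 = theta0, X3 = X3), class = "material_point")
}
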