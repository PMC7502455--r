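#' Convolution weights of the L1 Caputo scheme
#'
#' The Caputo fractional derivative of order \eqn{\alpha \in (0, 1)},
#' \deqn{D_t^\alpha f(t) = \frac{1}{\Gamma(1-\alpha)} \int_0^t
#'   (t - z)^{-\alpha} f'(z) \, dz,}
#' is discretised on a uniform grid by interpolating the history piecewise
#' linearly inside the memory integral (the L1 scheme).  This yields
#' \deqn{D^\alpha f(t_k) = \sum_{j=1}^{k} w_{k-j} \, (f_j - f_{j-1}), \qquad
#'   w_\ell = \frac{\Delta t^{-\alpha}}{\Gamma(2-\alpha)}
#'   \left[ (\ell+1)^{1-\alpha} - \ell^{1-\alpha} \right],}
#' with weights that are positive and decay with the lag \eqn{\ell}.  The
#' scheme is exact for linear histories and \eqn{O(\Delta t^{2-\alpha})}
#' accurate for smooth ones.  At \eqn{\alpha = 1} the weights collapse to the
#' backward difference \eqn{(f_k - f_{k-1}) / \Delta t}.
#'
#' @param alpha Fractional order in (0, 1].
#' @param n Number of time samples in the history.
#' @param dt Time step (s).
#' @return Numeric vector of `n - 1` weights, lag 0 first.
#' @export
caputo_weights <- function(alpha, n, dt) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(dt), length(dt) == 1L, dt > 0, n >= 2)
  if (alpha <= 0 || alpha > 1) {
    abort("`alpha` must lie in (0, 1]; alpha = 0 is handled as the identity map by `caputo_derivative()`.")
  }
  l <- seq_len(n - 1) - 1
  lower <- l^(1 - alpha)
  lower[1] <- 0  # lim_{a -> 1} 0^(1-a) = 0, but R evaluates 0^0 as 1
  dt^(-alpha) / gamma(2 - alpha) * ((l + 1)^(1 - alpha) - lower)
}

#' Caputo fractional derivative of a sampled history
#'
#' Applies the L1 scheme (see [caputo_weights()]) componentwise to a scalar
#' or multi-component history sampled on a uniform grid.  The full history is
#' retained (no short-memory truncation); the convolution is evaluated by
#' FFT.  The output has the same shape as the input and is zero at the first
#' sample.  The memory starts at the first sample, taken to be the static
#' preloaded state, so constant histories differentiate to zero.
#'
#' Two limiting orders interpolate between elastic and viscous behaviour:
#' `alpha = 0` is treated as the identity map on the history (a hyperelastic
#' contribution), a deliberate divergence from the literal Caputo limit
#' \eqn{f(t) - f(0)}; `alpha = 1` reduces to the backward-difference viscous
#' rate \eqn{\partial_t f}.
#'
#' @param values Numeric vector (one component) or matrix with one row per
#'   time sample and one column per component.
#' @param alpha Fractional order in \[0, 1\].
#' @param dt Time step (s).
#' @return Same shape as `values`.
#' @examples
#' dt <- 0.01; t <- seq(0, 2, by = dt)
#' d <- caputo_derivative(t, alpha = 0.3, dt = dt)
#' max(abs(d[-1] - t[-1]^0.7 / gamma(1.7)))  # closed form for f(t) = t
#' @export
caputo_derivative <- function(values, alpha, dt) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  vec <- is.null(dim(values))
  v <- if (vec) matrix(values, ncol = 1L) else as.matrix(values)
  if (nrow(v) < 1L) abort("history must be nonempty")
  if (alpha == 0) return(values)
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  if (n >= 2L) {
    w <- caputo_weights(alpha, n, dt)
    d <- v[-1L, , drop = FALSE] - v[-n, , drop = FALSE]
    out[-1L, ] <- .conv_columns(d, w)
  }
  if (vec) drop(out) else out
}

# FFT-based causal convolution of each column of `d` (length m) with kernel
# `w` (length m); returns the first m rows of the full convolution.
.conv_columns <- function(d, w) {
  m <- nrow(d)
  if (m == 1L) return(d * w[1L])
  L <- 2^ceiling(log2(2L * m))
  dp <- rbind(d, matrix(0, L - m, ncol(d)))
  wp <- c(w, rep(0, L - m))
  fw <- fft(wp)
  conv <- Re(mvfft(mvfft(dp) * fw, inverse = TRUE)) / L
  conv[seq_len(m), , drop = FALSE]
}

#' Steady-state harmonic response of the fractional operator
#'
#' For a sinusoidal input \eqn{\sin(\omega t)}, the Caputo derivative of
#' order \eqn{\alpha} tends (after the memory transient decays) to
#' \eqn{\omega^\alpha \sin(\omega t + \alpha\pi/2)}: a gain of
#' \eqn{\omega^\alpha} and a phase lead of \eqn{\alpha\pi/2}.  This is the
#' fractional power-law stiffening \eqn{G^* \propto \omega^\alpha} observed
#' in multi-frequency soft-tissue rheometry.
#'
#' @param omega Angular frequency (rad/s), positive.
#' @param alpha Fractional order.
#' @return Named vector `c(gain = omega^alpha, phase = alpha * pi / 2)`.
#' @export
steady_state_reference <- function(omega, alpha) {
  stopifnot(is.numeric(omega), omega > 0, is.numeric(alpha))
  c(gain = omega^alpha, phase = alpha * pi / 2)
}

#' Time for a power-law relaxation to reach a residual fraction
#'
#' A purely fractional viscoelastic term relaxes with the power law
#' \eqn{F = F_{max} t^{-\alpha}}; the time at which the response has decayed
#' to a fraction `fraction` of its maximum is `fraction^(-1/alpha)` seconds.
#' For \eqn{\alpha = 0.2} and a 1\% residual this is \eqn{10^{10}} s
#' (roughly 317 years), which is why a single fractional term behaves as
#' quasi-elastic on any practical experimental horizon.
#'
#' @param alpha Fractional order in (0, 1].
#' @param fraction Residual fraction of the maximum (default 0.01).
#' @return Time in seconds.
#' @examples
#' power_law_decay_time(0.2)  # 1e10 s
#' @export
power_law_decay_time <- function(alpha, fraction = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction < 1)
  fraction^(-1 / alpha)
}
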