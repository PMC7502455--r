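#' The 18-test compression / shear / frequency protocol
#'
#' The default study protocol crosses compressive preloads of 1, 10 and 20\%
#' with shear-strain amplitudes of 1, 10, 25 and 50\% at 1 Hz (12 tests),
#' and adds the 10\% preload cell at shear strains 1, 10 and 25\% at 0.5 Hz
#' and at 2 Hz (3 + 3 tests): 18 tests in all, 12 of them at 1 Hz.  Sample
#' geometry defaults to the nominal cylindrical specimen of 10 mm radius and
#' 3 mm height.
#'
#' @param height,radius Undeformed sample dimensions in metres.
#' @param points_per_period,n_burnin,n_record Sampling scheme per test (see
#'   [test_condition()]).
#' @return A tibble with one row per test: `test`, `cs_percent`,
#'   `shear_percent`, `freq_hz`, plus the geometry and sampling columns
#'   consumed by [generate_dataset()] and [sweep_fit()].
#' @examples
#' default_protocol()
#' @export
default_protocol <- function(height = 3e-3, radius = 10e-3,
                             points_per_period = 200, n_burnin = 8,
                             n_record = 3) {
  at_1hz <- tidyr::expand_grid(cs_percent = c(1, 10, 20),
                               shear_percent = c(1, 10, 25, 50),
                               freq_hz = 1)
  off_1hz <- tidyr::expand_grid(cs_percent = 10,
                                shear_percent = c(1, 10, 25),
                                freq_hz = c(0.5, 2))
  out <- dplyr::arrange(dplyr::bind_rows(at_1hz, off_1hz),
                        .data$freq_hz, .data$cs_percent, .data$shear_percent)
  tibble::tibble(test = seq_len(nrow(out)), out,
                 height_m = height, radius_m = radius,
                 points_per_period = as.integer(points_per_period),
                 n_burnin = as.integer(n_burnin),
                 n_record = as.integer(n_record))
}

#' Turn protocol rows into test conditions
#'
#' @param protocol A protocol tibble (see [default_protocol()]).
#' @return A list of [test_condition()] objects, one per row.
#' @export
protocol_conditions <- function(protocol) {
  p <- tibble::as_tibble(protocol)
  lapply(seq_len(nrow(p)), function(i) {
    test_condition(
      sample_geometry(p$height_m[i], p$radius_m[i], p$cs_percent[i] / 100),
      p$shear_percent[i] / 100, p$freq_hz[i],
      p$points_per_period[i], p$n_burnin[i], p$n_record[i])
  })
}

#' Strain-softening amplitude schedule
#'
#' Sequentially sheared tissue softens: the apparent linear parameters
#' decrease as the peak shear strain of prior loading grows.  In the
#' parameter-scaling formulation this is a per-test amplitude factor
#' \eqn{\beta_i > 0} with absolute parameters \eqn{x_i = x^* / \beta_i}, so
#' a *softer* test (smaller absolute parameters) carries a *larger*
#' \eqn{\beta_i}.
#'
#' `kind = "linear"` makes the absolute parameters fall linearly in the
#' shear amplitude, spanning a `range`-fold decrease (default 2) from the
#' smallest to the largest shear strain in the protocol, within every
#' (compression, frequency) group; `kind = "none"` gives \eqn{\beta_i = 1};
#' `kind = "custom"` passes `beta` through unchanged.
#'
#' @param protocol A protocol tibble (see [default_protocol()]).
#' @param kind `"none"`, `"linear"` or `"custom"`.
#' @param range Fold-decrease of the absolute parameters across the shear
#'   range (used by `"linear"`).
#' @param beta Numeric vector of per-test factors (used by `"custom"`).
#' @return Numeric vector of \eqn{\beta_i}, one per protocol row.
#' @export
softening_schedule <- function(protocol, kind = c("linear", "none", "custom"),
                               range = 2, beta = NULL) {
  kind <- match.arg(kind)
  p <- tibble::as_tibble(protocol)
  n <- nrow(p)
  if (kind == "none") return(rep(1, n))
  if (kind == "custom") {
    stopifnot(is.numeric(beta), length(beta) == n, all(beta > 0))
    return(beta)
  }
  stopifnot(is.numeric(range), length(range) == 1L, range >= 1)
  g <- p$shear_percent / 100
  g0 <- min(g); g1 <- max(g)
  soft <- if (g1 > g0) 1 - (1 - 1 / range) * (g - g0) / (g1 - g0) else rep(1, n)
  1 / soft
}

#' Generate a synthetic LAOS torque dataset with known ground truth
#'
#' Simulates every test of a protocol with the forward model, scales the
#' linear parameters of test \eqn{i} by \eqn{1/\beta_i} (strain softening as
#' a shape-preserving amplitude change), and adds i.i.d. Gaussian
#' measurement noise with standard deviation `noise_sd` times the per-test
#' torque amplitude.  The manifest attached to the result records
#' everything needed to regenerate the dataset bit-exactly under the same
#' seed.
#'
#' @param params True [material_parameters()] (the shared \eqn{x^*}-level
#'   parameters at \eqn{\beta = 1} gauge).
#' @param protocol A protocol tibble (default [default_protocol()]).
#' @param softening `"linear"`, `"none"`, or a numeric vector of per-test
#'   \eqn{\beta_i} factors.
#' @param noise_sd Noise level as a fraction of each test's torque
#'   amplitude (default 0.01).
#' @param seed RNG seed for the noise (optional; the generator is fully
#'   deterministic given the seed).
#' @param mesh Optional surface mesh for the forward model.
#' @return A tibble of class `laos_dataset`: the protocol columns plus
#'   `beta` and a `trace` list-column of tibbles (`time`, `angle`,
#'   `torque`, `tau_true`).  The ground truth is in `attr(, "manifest")`.
#' @examples
#' pars <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
#' ds <- generate_dataset(pars, default_protocol(points_per_period = 64)[1:2, ],
#'                        noise_sd = 0.01, seed = 42)
#' ds
#' @export
generate_dataset <- function(params, protocol = default_protocol(),
                             softening = "linear", noise_sd = 0.01,
                             seed = NULL, mesh = NULL) {
  stopifnot(inherits(params, "material_parameters"),
            is.numeric(noise_sd), noise_sd >= 0)
  p <- tibble::as_tibble(protocol)
  beta <- if (is.numeric(softening)) {
    softening_schedule(p, "custom", beta = softening)
  } else {
    softening_schedule(p, softening)
  }
  if (!is.null(seed)) set.seed(seed)
  conds <- protocol_conditions(p)
  traces <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    pi_ <- params
    pi_$delta <- params$delta / beta[i]
    if (!is.na(params$C_lin)) pi_$C_lin <- params$C_lin / beta[i]
    tr <- simulate_test(pi_, conds[[i]], mesh)
    amp <- max(abs(tr$tau))
    noise <- if (noise_sd > 0) rnorm(nrow(tr), sd = noise_sd * amp) else 0
    traces[[i]] <- tibble::tibble(time = tr$time, angle = tr$angle,
                                  torque = tr$tau + noise,
                                  tau_true = tr$tau)
  }
  out <- dplyr::mutate(p, beta = beta, trace = traces)
  class(out) <- c("laos_dataset", class(out))
  attr(out, "manifest") <- list(
    model = params$model,
    true_params = unclass(params),
    beta = beta, noise_sd = noise_sd, seed = seed,
    generated_by = paste0("laosfit ", as.character(utils::packageVersion("laosfit")))
  )
  out
}
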